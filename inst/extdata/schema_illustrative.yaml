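# Illustrative workload tariff — NOT the CAP-ACP L4E 2018 point table and
# NOT the Ontario Schedule of Benefits; point values here are placeholders
# for demonstration and testing. Edit freely or supply your own file.
version: illustrative-0.1
unmatched: error
metrics:
  - L4E
  - fees
  - blocks
  - cases
rules:
  - name: surgical
    case_class: surgical
    contributions:
      L4E: {base: 1.0, per_block: 0.8}
      fees: {base: 25, per_block: 12}
      blocks: {per_block: 1}
      cases: {base: 1}
  - name: cytology
    case_class: cytology
    contributions:
      L4E: {base: 0.6, per_specimen: 0.4}
      fees: {base: 15, per_specimen: 8}
      blocks: {per_block: 1}
      cases: {base: 1}
  - name: review_or_referral
    case_class: [review, external_referral]
    contributions:
      L4E: {base: 1.5}
      fees: {base: 20}
      blocks: {per_block: 1}
      cases: {base: 1}
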