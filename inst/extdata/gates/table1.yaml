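gates:
  CTC:
  - feature: mean
    channel: CD45
    op: <=
    threshold: 5.0
    units: AU
  - feature: mean
    channel: DAPI
    op: '>'
    threshold: 45.0
    units: AU
  - feature: mean
    channel: CK
    op: '>'
    threshold: 60.0
    units: AU
  - feature: size
    channel: CK
    op: '>'
    threshold: 16.0
    units: um2
  - feature: size
    channel: CK
    op: <=
    threshold: 400.0
    units: um2
  - feature: overlay_ck_dapi
    channel: CK
    op: '>'
    threshold: 0.2
    units: AU
  - feature: mean
    channel: M1
    op: <=
    threshold: 5.0
    units: AU
  - feature: mean
    channel: M2
    op: <=
    threshold: 5.0
    units: AU
  TDEV:
  - feature: mean
    channel: CD45
    op: <=
    threshold: 5.0
    units: AU
  - feature: mean
    channel: DAPI
    op: <=
    threshold: 5.0
    units: AU
  - feature: mean
    channel: CK
    op: '>'
    threshold: 60.0
    units: AU
  - feature: max
    channel: CK
    op: '>'
    threshold: 90.0
    units: AU
  - feature: area
    channel: CK
    op: <=
    threshold: 150.0
    units: um2
  - feature: eccentricity
    channel: CK
    op: <=
    threshold: 0.8
    units: AU
  - feature: perimeter_to_area
    channel: CK
    op: <=
    threshold: 1.0
    units: AU
  - feature: perimeter
    channel: CK
    op: '>'
    threshold: 5.0
    units: pixels
  - feature: size
    channel: CK
    op: <=
    threshold: 150.0
    units: um2
  - feature: mean
    channel: M1
    op: <=
    threshold: 5.0
    units: AU
  - feature: mean
    channel: M2
    op: <=
    threshold: 5.0
    units: AU
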