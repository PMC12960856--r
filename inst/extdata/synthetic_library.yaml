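# Synthetic ECMO component library.
# Coefficient values are invented but shape-plausible (smaller cannulas are
# steeper; higher pump speeds raise the shut-off head). They are NOT any
# manufacturer's published characteristics. Identical to the library
# returned by ecmoflow::default_component_library(), except that the
# 18 Fr drainage cannula is fitted from the accompanying catalog CSV to
# demonstrate point-file loading.
components:
  - name: drain_18fr
    kind: drainage_cannula
    points_file: drain_18fr_catalog.csv
    size_fr: 18
  - name: drain_22fr
    kind: drainage_cannula
    k1: 1.4
    k2: 2.5
    k3: 0
    size_fr: 22
  - name: return_14fr
    kind: return_cannula
    k1: 6.5
    k2: 9.0
    k3: 0
    size_fr: 14
  - name: return_18fr
    kind: return_cannula
    k1: 2.8
    k2: 5.0
    k3: 0
    size_fr: 18
  - name: oxygenator
    kind: oxygenator
    k1: 0.8
    k2: 4.0
    k3: 0
  - name: tube1
    kind: connecting_tube
    k1: 2.0    # 0.5 m of 3/8-inch tubing at 4 mmHg min^2/L^2 per metre
    k2: 0
    k3: 0
    length_m: 0.5
  - name: tube2
    kind: connecting_tube
    k1: 2.0
    k2: 0
    k3: 0
    length_m: 0.5
  - name: tube3
    kind: connecting_tube
    k1: 4.0
    k2: 0
    k3: 0
    length_m: 1.0
pumps:
  - name: centrifugal
    curves:
      '2500': {k1: -2.0, k2: -3.0, k3: 180}
      '3000': {k1: -2.0, k2: -3.0, k3: 260}
      '3500': {k1: -2.0, k2: -3.0, k3: 350}
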