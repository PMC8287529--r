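implant:
  head_diameter: 48.0
  mismatch: 8.0
  insert_thickness: 5.0
  coverage_angle: 60.0
  mesh_resolution: 2000.0
arm:
  mass: 4.0
  com:
  - 0.0
  - -0.3
  - 0.0
spring:
  stiffness: 17400.0
  rest_point:
  - 0.0
  - 0.0
  - 0.0
contact:
  P_V: 2.74e+11
  eps_o: 0.0597
  p_o: 18.4
  'n': 3.0
  v: 0.46
recruitment:
  criterion_order: 2.0
rhythm: 1.0
muscles: default_muscles.csv
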