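w_R: 1.0
remainder_organ_count: 13
organs:
- organ: bone_marrow
  w_T: 0.12
  is_remainder: no
  substructures:
  - name: ulna
    f_i: 0.0019
    dosimeters:
    - 7
    - 8
    - 10
    - 11
  - name: radius
    f_i: 0.0021
    dosimeters:
    - 6
    - 8
    - 10
    - 11
  - name: humerus
    f_i: 0.006
    dosimeters:
    - 1
    - 2
    - 5
    - 6
- organ: bone_surface
  w_T: 0.01
  is_remainder: no
  substructures:
  - name: ulna
    f_i: 0.004
    dosimeters:
    - 6
    - 9
  - name: radius
    f_i: 0.0039
    dosimeters:
    - 6
    - 9
  - name: humerus
    f_i: 0.0093
    dosimeters:
    - 1
    - 2
    - 5
    - 6
- organ: skin
  w_T: 0.01
  is_remainder: no
  substructures:
  - name: flexor_carpi_ulnaris
    f_i: 0.0083
    dosimeters: 9
  - name: extensor_carpi_radialis_longus
    f_i: 0.008
    dosimeters: 8
  - name: bicep
    f_i: 0.0081
    dosimeters: 4
  - name: tricep
    f_i: 0.0042
    dosimeters: 3
- organ: lymphatic_nodes
  w_T: 0.12
  is_remainder: yes
  substructures:
  - name: cubital_nodes
    f_i: 0.05
    dosimeters: 6
- organ: muscle
  w_T: 0.12
  is_remainder: yes
  substructures:
  - name: flexor_carpi_ulnaris
    f_i: 0.0004
    dosimeters: 9
  - name: extensor_carpi_radialis_longus
    f_i: 0.0005
    dosimeters: 6
  - name: brachioradialis
    f_i: 0.0018
    dosimeters: 6
  - name: bicep
    f_i: 0.0022
    dosimeters: 4
  - name: tricep
    f_i: 0.004
    dosimeters: 3
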