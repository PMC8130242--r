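layer_thickness_cm: 2.5
exposed_layers:
- 11
- 12
- 13
- 14
- 15
- 16
- 17
layers:
- layer: 10
  perimeter_cm: 28.0
  bones:
    ulna: 0.48
    radius: 0.53
  muscles:
    flexor_carpi_ulnaris: 3.0
- layer: 11
  perimeter_cm: 28.4
  bones:
    ulna: 0.5
    radius: 0.55
  muscles:
    flexor_carpi_ulnaris: 4.0
    extensor_carpi_radialis_longus: 5.0
- layer: 12
  perimeter_cm: 29.0
  bones:
    ulna: 0.53
    radius: 0.59
  muscles:
    flexor_carpi_ulnaris: 4.0
    extensor_carpi_radialis_longus: 5.0
    brachioradialis: 17.0
- layer: 13
  perimeter_cm: 29.8
  bones:
    ulna: 0.55
    radius: 0.61
  muscles:
    flexor_carpi_ulnaris: 3.2
    extensor_carpi_radialis_longus: 4.0
    brachioradialis: 17.0
- layer: 14
  perimeter_cm: 31.0
  bones:
    ulna: 0.575
    radius: 0.632
  muscles:
    brachioradialis: 16.4
- layer: 15
  perimeter_cm: 31.9
  bones:
    humerus: 2.1
  muscles:
    bicep: 22.0
    tricep: 40.0
- layer: 16
  perimeter_cm: 32.6
  bones:
    humerus: 2.3
  muscles:
    bicep: 22.0
    tricep: 40.0
- layer: 17
  perimeter_cm: 33.4
  bones:
    humerus: 2.405
  muscles:
    bicep: 17.6
    tricep: 32.0
- layer: 18
  perimeter_cm: 34.0
  bones:
    humerus: 2.5
  muscles:
    tricep: 20.0
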