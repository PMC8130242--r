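[
  {
    "protocol_id": "shimadzu_fh21",
    "device": "Shimadzu FH-21 HR",
    "modality": "radiography",
    "setting": "AP+LAT",
    "kVp": 59,
    "mAs": 12.6,
    "fov": "13x16",
    "ctdi_vol_mGy": null,
    "dlp_mGy_cm": null
  },
  {
    "protocol_id": "siemens_sensation",
    "device": "Siemens Sensation Open",
    "modality": "MSCT",
    "setting": "standard",
    "kVp": 120,
    "mAs": 115,
    "fov": "13x16",
    "ctdi_vol_mGy": 11,
    "dlp_mGy_cm": 179
  },
  {
    "protocol_id": "newtom5g_hires_12x8",
    "device": "NewTom 5G",
    "modality": "CBCT",
    "setting": "HiRes",
    "kVp": 110,
    "mAs": 27.7,
    "fov": "12x8",
    "ctdi_vol_mGy": 4.4,
    "dlp_mGy_cm": 39.6
  },
  {
    "protocol_id": "newtom5g_std_12x8",
    "device": "NewTom 5G",
    "modality": "CBCT",
    "setting": "Standard Scan",
    "kVp": 110,
    "mAs": 3.5,
    "fov": "12x8",
    "ctdi_vol_mGy": 1.16,
    "dlp_mGy_cm": 10.5
  },
  {
    "protocol_id": "newtom5g_std_15x12",
    "device": "NewTom 5G",
    "modality": "CBCT",
    "setting": "Standard Scan",
    "kVp": 110,
    "mAs": 2.6,
    "fov": "15x12",
    "ctdi_vol_mGy": 1.15,
    "dlp_mGy_cm": 14.7
  },
  {
    "protocol_id": "newtom5g_std_18x16",
    "device": "NewTom 5G",
    "modality": "CBCT",
    "setting": "Standard Scan",
    "kVp": 110,
    "mAs": 2.4,
    "fov": "18x16",
    "ctdi_vol_mGy": 1.14,
    "dlp_mGy_cm": 18.2
  },
  {
    "protocol_id": "planmed_verity",
    "device": "Planmed Verity",
    "modality": "CBCT",
    "setting": "ULD",
    "kVp": 92,
    "mAs": 22.5,
    "fov": "13x16",
    "ctdi_vol_mGy": null,
    "dlp_mGy_cm": null
  }
]
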