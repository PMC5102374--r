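{
  "schema": ["size_length_um", "shape", "peristome_extent_pct", "AZM_membranelles", "dorsal_ridges", "dargyrome_type", "FVC_count", "dorsolateral_kineties", "middorsal_dikinetids"],
  "profiles": [
    {
      "name": "Euplotes_curdsi",
      "provenance": "original description",
      "traits": {
        "size_length_um": [45, 65],
        "shape": ["oval", "ellipsoid"],
        "peristome_extent_pct": [63, 77],
        "AZM_membranelles": [25, 34],
        "dorsal_ridges": "inconspicuous",
        "dargyrome_type": "double-eurystomus",
        "FVC_count": [10, 10],
        "dorsolateral_kineties": [6, 7],
        "middorsal_dikinetids": [10, 12]
      }
    },
    {
      "name": "Euplotes_antarcticus",
      "provenance": "literature",
      "traits": {
        "size_length_um": [76.5, 93.5],
        "shape": ["elongated", "pointed-posterior"],
        "peristome_extent_pct": [67.5, 82.5],
        "AZM_membranelles": [27, 33],
        "dorsal_ridges": "prominent",
        "dargyrome_type": null,
        "FVC_count": [10, 10],
        "dorsolateral_kineties": [8, 8],
        "middorsal_dikinetids": [11.7, 14.3]
      }
    },
    {
      "name": "Euplotes_magnicirratus",
      "provenance": "literature",
      "traits": {
        "size_length_um": [51, 65],
        "shape": "oval",
        "peristome_extent_pct": [67.5, 82.5],
        "AZM_membranelles": [49, 52],
        "dorsal_ridges": "prominent",
        "dargyrome_type": "double-eurystomus",
        "FVC_count": [10, 10],
        "dorsolateral_kineties": [8, 8],
        "middorsal_dikinetids": [13, 17]
      }
    },
    {
      "name": "Euplotes_alatus",
      "provenance": "literature",
      "traits": {
        "size_length_um": [36, 43],
        "shape": "oval",
        "peristome_extent_pct": [45, 55],
        "AZM_membranelles": [23.4, 28.6],
        "dorsal_ridges": "inconspicuous",
        "dargyrome_type": "double-eurystomus",
        "FVC_count": [10, 10],
        "dorsolateral_kineties": [8, 8],
        "middorsal_dikinetids": [10, 12]
      }
    },
    {
      "name": "Euplotes_trisulcatus",
      "provenance": "literature",
      "traits": {
        "size_length_um": [35, 50],
        "shape": ["elongated", "pointed-posterior"],
        "peristome_extent_pct": [58.5, 71.5],
        "AZM_membranelles": [25, 36],
        "dorsal_ridges": "prominent",
        "dargyrome_type": "double-eurystomus",
        "FVC_count": [10, 10],
        "dorsolateral_kineties": [7, 7],
        "middorsal_dikinetids": [9.9, 12.1]
      }
    },
    {
      "name": "Euplotes_balteatus",
      "provenance": "literature",
      "traits": {
        "size_length_um": [30, 150],
        "shape": "oval",
        "peristome_extent_pct": [63, 77],
        "AZM_membranelles": [25, 80],
        "dorsal_ridges": "prominent",
        "dargyrome_type": "double-eurystomus",
        "FVC_count": [10, 10],
        "dorsolateral_kineties": [7, 8],
        "middorsal_dikinetids": [10, 16]
      }
    }
  ]
}
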