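{
  "comment": "Reference per-cell-line MLR equations and their reported performance statistics. citation strings locate each value in the source report.",
  "models": [
    {
      "cell_line": "HuCCA-1",
      "term1": "R5e+", "coef1": -84.0157,
      "term2": "nArCOOR", "coef2": 1.0288,
      "intercept": 0.8738,
      "N": 13, "R_Tr": 0.9597, "RMSE_Tr": 0.1603,
      "R_CV": 0.8957, "RMSE_CV": 0.2562,
      "citation": "Table 3",
      "notes": null
    },
    {
      "cell_line": "HepG2",
      "term1": "RDF105m", "coef1": 0.0784,
      "term2": "MATS7m", "coef2": 5.1878,
      "intercept": -1.7524,
      "N": 24, "R_Tr": 0.7537, "RMSE_Tr": 0.4006,
      "R_CV": 0.6724, "RMSE_CV": 0.4526,
      "citation": "Table 3",
      "notes": "Intercept sign conflicts between the running-text equation (+1.7524) and Table 3 (-1.7524); -1.7524 is used because only it is consistent with positive RDF105m/MATS7m values yielding the reported predicted pIC50 range."
    },
    {
      "cell_line": "A549",
      "term1": "MATS8v", "coef1": 1.5979,
      "term2": "nArCOOR", "coef2": 0.9251,
      "intercept": -1.7829,
      "N": 16, "R_Tr": 0.8673, "RMSE_Tr": 0.2390,
      "R_CV": 0.5958, "RMSE_CV": 0.4211,
      "citation": "Table 3",
      "notes": null
    },
    {
      "cell_line": "MOLT-3",
      "term1": "Lop", "coef1": 1.0649,
      "term2": "R7m", "coef2": 10.3977,
      "intercept": -5.6832,
      "N": 20, "R_Tr": 0.8936, "RMSE_Tr": 0.1714,
      "R_CV": 0.8430, "RMSE_CV": 0.2070,
      "citation": "Table 3",
      "notes": null
    }
  ]
}
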