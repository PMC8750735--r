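{
  "name": "LSM",
  "missing_token": "NA",
  "missing_category": "(missing)",
  "bin_convention": "lower-inclusive / upper-exclusive; final bin unbounded above",
  "variables": [
    {"name": "Race", "kind": "raw-categorical",
     "categories": ["White", "Black", "Asian", "American Indian or Alaskan native", "native Hawaiian or other Pacific islander"]},
    {"name": "Ethnicity", "kind": "raw-categorical",
     "categories": ["Not Hispanic", "Hispanic"]},
    {"name": "Smoking", "kind": "raw-categorical",
     "categories": ["Ex-smoker", "non-smoker", "cigarettes", "chewing tobacco", "cigar"]},
    {"name": "Alcohol usage", "kind": "raw-categorical",
     "categories": ["Moderate", "no use", "use but not otherwise specified former user", "heavy user"]},
    {"name": "Family history", "kind": "raw-categorical",
     "categories": ["Cancer", "no cancer", "breast cancer", "other cancer", "cancer but not otherwise specified"]},
    {"name": "Age_at_diagnosis", "kind": "binned-numeric",
     "categories": ["0-49", "50-69", ">69"], "bin_edges": [0, 50, 70]},
    {"name": "Menopausal_status", "kind": "raw-categorical",
     "categories": ["Pre-", "post-"]},
    {"name": "Side", "kind": "raw-categorical",
     "categories": ["Left", "right"]},
    {"name": "TNEG", "kind": "raw-categorical",
     "categories": ["Yes", "no"]},
    {"name": "ER", "kind": "raw-categorical",
     "categories": ["Neg", "pos", "low pos"]},
    {"name": "ER_percent", "kind": "binned-numeric",
     "categories": ["0-20", "20-90", "90-100"], "bin_edges": [0, 20, 90]},
    {"name": "PR", "kind": "raw-categorical",
     "categories": ["Neg", "pos", "low pos"]},
    {"name": "PR_percent", "kind": "binned-numeric",
     "categories": ["0-20", "20-90", "90-100"], "bin_edges": [0, 20, 90]},
    {"name": "P53", "kind": "raw-categorical",
     "categories": ["Neg", "pos", "low pos"]},
    {"name": "HER2", "kind": "raw-categorical",
     "categories": ["Neg", "pos"]},
    {"name": "t_tnm_stage", "kind": "raw-categorical",
     "categories": ["0", "1", "2", "3", "4", "IS", "1 mic", "X"]},
    {"name": "n_tnm_stage", "kind": "raw-categorical",
     "categories": ["0", "1", "2", "3", "4", "X"]},
    {"name": "Stage", "kind": "raw-categorical",
     "categories": ["0", "1", "2", "3"]},
    {"name": "Lymph_nodes_removed", "kind": "binned-numeric",
     "categories": ["0-11", "12-22", ">22"], "bin_edges": [0, 12, 23]},
    {"name": "Lymph_nodes_positive", "kind": "binned-numeric",
     "categories": ["0", "1-8", ">8"], "bin_edges": [0, 1, 9]},
    {"name": "Lymph_node_status", "kind": "raw-categorical",
     "categories": ["Neg", "pos"]},
    {"name": "Histology", "kind": "raw-categorical",
     "categories": ["Lobular", "ductal"]},
    {"name": "Size", "kind": "binned-numeric",
     "categories": ["0-32", "32-70", ">70"], "bin_edges": [0, 32, 70]},
    {"name": "Grade", "kind": "raw-categorical",
     "categories": ["1", "2", "3"]},
    {"name": "Invasive", "kind": "raw-categorical",
     "categories": ["Yes", "no"]},
    {"name": "Histology2", "kind": "raw-categorical",
     "categories": ["IDC", "DCIS", "ILC", "NC"]},
    {"name": "Invasive_tumor_location", "kind": "raw-categorical",
     "categories": ["Mixed duct and lobular", "duct", "lobular", "none"]},
    {"name": "DCIS_level", "kind": "raw-categorical",
     "categories": ["Solid", "apocrine", "cribriform", "dcis", "comedo", "papillary", "micropapillary"]},
    {"name": "Re_excision", "kind": "raw-categorical",
     "categories": ["Yes", "no"]},
    {"name": "Surgical_margins", "kind": "raw-categorical",
     "categories": ["Residual tumor", "no residual tumor", "no primary site surgery"]},
    {"name": "MRIs_60_surgery", "kind": "raw-categorical",
     "categories": ["Yes", "no"]}
  ],
  "outcomes": [
    {"name": "Metastasis_5yr",  "horizon": 5,  "categories": ["no", "yes"]},
    {"name": "Metastasis_10yr", "horizon": 10, "categories": ["no", "yes"]},
    {"name": "Metastasis_15yr", "horizon": 15, "categories": ["no", "yes"]}
  ]
}
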