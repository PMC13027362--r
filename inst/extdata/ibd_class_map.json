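{
  "designated": [
    "immunomodulatory imide",
    "monoclonal antibody immunotherapy",
    "cytotoxic immunosuppressant",
    "sphingosine-1-phosphate modulator",
    "fumarate immunomodulator",
    "PDE4 inhibitor immunomodulator",
    "tyrosine kinase inhibitor",
    "peptide copolymer immunomodulator",
    "interferon immunomodulator"
  ],
  "classes": {
    "Lenalidomide": "immunomodulatory imide",
    "Dupilumab": "monoclonal antibody immunotherapy",
    "Cyclophosphamide": "cytotoxic immunosuppressant",
    "Fingolimod": "sphingosine-1-phosphate modulator",
    "Dimethyl fumarate": "fumarate immunomodulator",
    "Apremilast": "PDE4 inhibitor immunomodulator",
    "Imatinib": "tyrosine kinase inhibitor",
    "Glatiramer acetate": "peptide copolymer immunomodulator",
    "Interferon beta-1a": "interferon immunomodulator",
    "Risperidone": "antipsychotic",
    "Clozapine": "antipsychotic",
    "Aripiprazole": "antipsychotic",
    "Quetiapine": "antipsychotic",
    "Levetiracetam": "anticonvulsant",
    "Lamotrigine": "anticonvulsant",
    "Carbamazepine": "anticonvulsant",
    "Topiramate": "anticonvulsant",
    "Pregabalin": "anticonvulsant",
    "Gabapentin": "anticonvulsant",
    "Dulaglutide": "GLP-1 receptor agonist",
    "Liraglutide": "GLP-1 receptor agonist",
    "Semaglutide": "GLP-1 receptor agonist",
    "Insulin lispro": "insulin",
    "Insulin glargine": "insulin",
    "Insulin aspart": "insulin",
    "Insulin": "insulin",
    "Varenicline": "smoking-cessation agent",
    "Valsartan": "angiotensin receptor blocker",
    "Losartan": "angiotensin receptor blocker",
    "Irbesartan": "angiotensin receptor blocker",
    "Rivaroxaban": "anticoagulant",
    "Apixaban": "anticoagulant",
    "Warfarin": "anticoagulant",
    "Enoxaparin": "anticoagulant",
    "Clopidogrel": "antiplatelet",
    "Carvedilol": "beta blocker",
    "Metoprolol": "beta blocker",
    "Atenolol": "beta blocker",
    "Propranolol": "beta blocker",
    "Bisoprolol": "beta blocker",
    "Atorvastatin calcium": "statin",
    "Atorvastatin": "statin",
    "Simvastatin": "statin",
    "Pravastatin": "statin",
    "Rosuvastatin calcium": "statin",
    "Empagliflozin": "SGLT2 inhibitor",
    "Metformin": "biguanide antidiabetic",
    "Sitagliptin": "DPP-4 inhibitor",
    "Lisinopril": "ACE inhibitor",
    "Enalapril": "ACE inhibitor",
    "Somatotropin": "growth hormone",
    "Diazepam": "benzodiazepine",
    "Alprazolam": "benzodiazepine",
    "Temazepam": "benzodiazepine",
    "Clonazepam": "benzodiazepine",
    "Fenofibrate": "fibrate",
    "Nifedipine": "calcium channel blocker",
    "Verapamil": "calcium channel blocker",
    "Diltiazem": "calcium channel blocker",
    "Amlodipine": "calcium channel blocker",
    "Fexofenadine": "antihistamine",
    "Hydroxyzine": "antihistamine",
    "Spironolactone": "potassium-sparing diuretic",
    "Clonidine": "alpha-2 agonist",
    "Metoclopramide": "prokinetic antiemetic",
    "Naltrexone": "opioid antagonist",
    "Fluconazole": "antifungal",
    "Nitroglycerin": "nitrate vasodilator",
    "Octreotide": "somatostatin analogue",
    "Allopurinol": "xanthine oxidase inhibitor",
    "Melatonin": "hormone supplement",
    "Famotidine": "H2 receptor antagonist",
    "Venlafaxine": "antidepressant"
  }
}
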