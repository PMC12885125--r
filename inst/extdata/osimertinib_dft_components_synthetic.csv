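# Synthetic single-point component energies (kcal/mol) for osimertinib
# bound to EGFR kinase-domain crystal structures. The absolute component
# values are invented stand-ins for quantum-chemistry output; only their
# differences are meaningful, and those reproduce published DFT
# binding-energy estimates for these complexes.
label,variant,e_complex,e_protein,e_ligand,note
6JXT,WT,-2425517.57,-2103200.00,-321740.00,covalent bond with osimertinib
6JX0,T790M,-2427024.45,-2104750.00,-321740.00,protein co-crystalized with osimertinib
6JWL,L858R,-2424719.87,-2102480.00,-321740.00,protein crystal soaked with osimertinib
4ZAU,WT,-2424039.33,-2101890.00,-321740.00,no covalent bond with osimertinib
6JX4,T790M,-2427296.95,-2105630.00,-321740.00,protein crystal soaked with osimertinib
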