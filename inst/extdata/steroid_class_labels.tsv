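class
Androgen
Antiandrogen
Antiestrogen
Antiprogestogen
Bile Acid
Cardiac Glycoside
Enzyme
Estrogen
Glucocorticoid
Mineralocorticoid
Mineralocorticoid Receptor Antagonist
Non-steroidal Neuromuscular Blocker
Phytosteroid
Progestogen
Steroid (General)
Steroidal Antibiotic
Steroidal Aromatase Inhibitor
Sterol
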