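drug_name	class
DANAZOL	Androgen
METHYLTESTOSTERONE	Androgen
TESTOSTERONE	Androgen
CYPROTERONE	Antiandrogen
FULVESTRANT	Antiestrogen
URSODEOXYCHOLIC ACID	Bile Acid
DIGITOXIN	Cardiac Glycoside
DIGOXIN	Cardiac Glycoside
METILDIGOXIN	Cardiac Glycoside
ESTRADIOL	Estrogen
ESTRAMUSTINE	Estrogen
ETHINYLESTRADIOL	Estrogen
ESTRIOL	Estrogen
ESTROGENS CONJUGATED	Estrogen
BETAMETHASONE	Glucocorticoid
CLOBETASONE	Glucocorticoid
DEXAMETHASONE	Glucocorticoid
FLUMETASONE	Glucocorticoid
METHYLPREDNISOLONE	Glucocorticoid
CORTISONE	Glucocorticoid
HYDROCORTISONE	Glucocorticoid
PREDNISOLONE	Glucocorticoid
PREDNISONE	Glucocorticoid
DIFLUCORTOLONE	Glucocorticoid
BUDESONIDE	Glucocorticoid
DESOXIMETASONE	Glucocorticoid
CICLESONIDE	Glucocorticoid
FLUNISOLIDE	Glucocorticoid
LOTEPREDNOL	Glucocorticoid
FLUDROCORTISONE	Mineralocorticoid
CANRENOIC ACID	Mineralocorticoid Receptor Antagonist
EPLERENONE	Mineralocorticoid Receptor Antagonist
SPIRONOLACTONE	Mineralocorticoid Receptor Antagonist
ROCURONIUM	Non-steroidal Neuromuscular Blocker
VECURONIUM	Non-steroidal Neuromuscular Blocker
DESOGESTREL	Progestogen
MEGESTROL	Progestogen
GESTODENE	Progestogen
NORGESTREL	Progestogen
CHLORMADINONE	Progestogen
DIENOGEST	Progestogen
NORELGESTROMIN	Progestogen
NORGESTIMATE	Progestogen
DROSPIRENONE	Progestogen
ETONOGESTREL	Progestogen
NORETHISTERONE	Progestogen
MEDROXYPROGESTERONE	Progestogen
STEROIDS	Steroid (General)
FUSIDIC ACID	Steroidal Antibiotic
EXEMESTANE	Steroidal Aromatase Inhibitor
CHOLESTEROL	Sterol
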