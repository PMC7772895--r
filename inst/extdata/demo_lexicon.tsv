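concept_id	term	semantic_type	is_preferred
C0010054	coronary artery disease	T047	1
C0010054	CAD	T047	0
C0027051	myocardial infarction	T047	1
C0027051	MI	T047	0
C0020538	hypertension	T047	1
C0020538	HTN	T047	0
C0011849	diabetes mellitus	T047	1
C0011849	diabetes	T047	0
C2316810	chronic kidney disease stage 5	T047	1
C2316810	end-stage renal disease	T047	0
C2316810	ESRD	T047	0
C0004096	asthma	T047	1
C0024117	chronic obstructive pulmonary disease	T047	1
C0024117	COPD	T047	0
C0038454	cerebrovascular accident	T047	1
C0038454	stroke	T047	0
C0018802	congestive heart failure	T047	1
C0018802	CHF	T047	0
C0003864	arthritis	T047	1
C0020676	hypothyroidism	T047	1
C0034065	pulmonary embolism	T047	1
C0032285	pneumonia	T047	1
C0023890	cirrhosis	T047	1
C0020473	hyperlipidemia	T047	1
C0004238	atrial fibrillation	T047	1
C0017168	gastroesophageal reflux disease	T047	1
C0017168	GERD	T047	0
C0011581	depression	T048	1
C0003467	anxiety	T048	1
C0028043	nicotine dependence	T048	1
C0028043	tobacco use disorder	T048	0
C0001973	alcoholism	T048	1
C0001973	alcohol abuse	T048	0
C0019080	hemorrhage	T046	1
C0036572	seizure	T046	1
C0149871	deep vein thrombosis	T046	1
C0149871	DVT	T046	0
C0006142	breast cancer	T191	1
C0007131	non-small cell lung cancer	T191	1
C0007131	NSCLC	T191	0
C0684249	lung cancer	T191	1
C0029925	ovarian cancer	T191	1
C0033578	prostate cancer	T191	1
C0033578	neoplasm of prostate	T191	0
C0699885	bladder cancer	T191	1
C0007102	colon cancer	T191	1
C0740457	renal cancer	T191	1
C0220650	brain metastasis	T191	1
C0025202	melanoma	T191	1
C0023418	leukemia	T191	1
C0003611	appendectomy	T062	1
C0020699	hysterectomy	T062	1
C0010055	coronary artery bypass graft	T062	1
C0010055	CABG	T062	0
C0259785	lobectomy	T062	1
C0040145	tonsillectomy	T062	1
C0008320	cholecystectomy	T062	1
C0150083	knee arthroscopy	T062	1
C0003896	arthroscopy	T062	1
C0019974	hernia repair	T062	1
C3665472	chemotherapy	T062	1
C1522449	radiation therapy	T062	1
C1522449	XRT	T062	0
C2939181	wedge resection	T062	1
C0086511	total knee replacement	T062	1
C0024881	mastectomy	T062	1
C0009378	colonoscopy	T060	1
C0194804	prostate biopsy	T060	1
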