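vocabulary	code	preferred_name	synonyms
RxNorm	56946	Paclitaxel	taxol
RxNorm	194000	Capecitabine	xeloda
SNOMED-CT	26929004	Alzheimer Disease	alzheimer's disease;alzheimers disease
SNOMED-CT	399326009	Urinary bladder neoplasms	bladder neoplasm;tumor of bladder
SNOMED-CT	69896004	Arthritis, Rheumatoid	rheumatoid arthritis
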