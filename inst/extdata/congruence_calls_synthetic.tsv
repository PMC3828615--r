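mirna_id	method	status	assessed
mir205	SSH	UP	TRUE
mir141	SSH	DOWN	TRUE
mir21	SSH	DOWN	TRUE
mir29c	SSH	DOWN	TRUE
mir100	SSH	NEUTRAL	TRUE
mir143	SSH	NEUTRAL	TRUE
let7c	SSH	NEUTRAL	TRUE
mir103	SSH	NEUTRAL	TRUE
mir183	SSH	NEUTRAL	TRUE
mir222	SSH	NEUTRAL	TRUE
mir205	MA	UP	TRUE
mir21	MA	DOWN	TRUE
mir100	MA	NEUTRAL	TRUE
mir125b	MA	NEUTRAL	TRUE
mir199a	MA	NEUTRAL	TRUE
mir145	MA	NEUTRAL	TRUE
mir203	MA	NEUTRAL	TRUE
mir222	MA	NEUTRAL	TRUE
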