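name	status	type	references	note
mir205	CONTRADICTORY	EXPRESSION	synthetic citation: reported up-regulated|synthetic citation: reported down-regulated	
mir199a2	UP	EXPRESSION	synthetic citation	
mir103	UP	EXPRESSION	synthetic citation	
mir183	UP	EXPRESSION	synthetic citation	
mir200a	CONTRADICTORY	EXPRESSION	synthetic citation: reported up-regulated|synthetic citation: reported down-regulated	
mir203	CONTRADICTORY	EXPRESSION	synthetic citation: reported up-regulated|synthetic citation: reported down-regulated	
mir222	UP	EXPRESSION	synthetic citation	
mirsyn01	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn02	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn03	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn04	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn05	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn06	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn07	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn08	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn09	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn10	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn11	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn12	UP	EXPRESSION	synthetic citation	synthetic filler
mir100	CONTRADICTORY	EXPRESSION	synthetic citation: reported up-regulated|synthetic citation: reported down-regulated	FGFR3 pathway
mir125b	DOWN	EXPRESSION	synthetic citation	p53 pathway
mir143	DOWN	EXPRESSION	synthetic citation	FGFR3 pathway
let7c	DOWN	EXPRESSION	synthetic citation	
mir141	CONTRADICTORY	EXPRESSION	synthetic citation: reported up-regulated|synthetic citation: reported down-regulated	
mir199a	DOWN	EXPRESSION	synthetic citation	
mir29c	DOWN	EXPRESSION	synthetic citation	
mir30c	DOWN	EXPRESSION	synthetic citation	
mir99a	DOWN	EXPRESSION	synthetic citation	
mir145	DOWN	EXPRESSION	synthetic citation	
mir101	DOWN	EXPRESSION	synthetic citation	
mir29	DOWN	EXPRESSION	synthetic citation	
mir125	DOWN	EXPRESSION	synthetic citation	
mir223	DOWN	EXPRESSION	synthetic citation	p53 pathway
mir21	UP	EXPRESSION	synthetic citation	
mir10	UP	EXPRESSION	synthetic citation	
mir30a	DOWN	EXPRESSION	synthetic citation	
mir126	DOWN	EXPRESSION	synthetic citation	
mir199b	UP	EXPRESSION	synthetic citation	
mir34a	DOWN	EXPRESSION	synthetic citation	
mir493	DOWN	EXPRESSION	synthetic citation	
mir26b	UP	EXPRESSION	synthetic citation	
mir146a	DOWN	EXPRESSION	synthetic citation	
mir7	DOWN	EXPRESSION	synthetic citation	
mir129	UP	EXPRESSION	synthetic citation	
mir30	DOWN	EXPRESSION	synthetic citation	
mirsyn13	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn14	DOWN	EXPRESSION	synthetic citation	synthetic filler
mirsyn15	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn16	DOWN	EXPRESSION	synthetic citation	synthetic filler
mirsyn17	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn18	DOWN	EXPRESSION	synthetic citation	synthetic filler
mirsyn19	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn20	DOWN	EXPRESSION	synthetic citation	synthetic filler
mirsyn21	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn22	DOWN	EXPRESSION	synthetic citation	synthetic filler
mirsyn23	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn24	DOWN	EXPRESSION	synthetic citation	synthetic filler
mirsyn25	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn26	DOWN	EXPRESSION	synthetic citation	synthetic filler
mirsyn27	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn28	DOWN	EXPRESSION	synthetic citation	synthetic filler
mirsyn29	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn30	DOWN	EXPRESSION	synthetic citation	synthetic filler
mirsyn31	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn32	DOWN	EXPRESSION	synthetic citation	synthetic filler
mirsyn33	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn34	DOWN	EXPRESSION	synthetic citation	synthetic filler
mirsyn35	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn36	DOWN	EXPRESSION	synthetic citation	synthetic filler
mirsyn37	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn38	DOWN	EXPRESSION	synthetic citation	synthetic filler
mirsyn39	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn40	DOWN	EXPRESSION	synthetic citation	synthetic filler
mirsyn41	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn42	DOWN	EXPRESSION	synthetic citation	synthetic filler
mirsyn43	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn44	DOWN	EXPRESSION	synthetic citation	synthetic filler
mirsyn45	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn46	DOWN	EXPRESSION	synthetic citation	synthetic filler
mirsyn47	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn48	DOWN	EXPRESSION	synthetic citation	synthetic filler
mirsyn49	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn50	DOWN	EXPRESSION	synthetic citation	synthetic filler
mirsyn51	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn52	DOWN	EXPRESSION	synthetic citation	synthetic filler
mirsyn53	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn54	DOWN	EXPRESSION	synthetic citation	synthetic filler
mirsyn55	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn56	DOWN	EXPRESSION	synthetic citation	synthetic filler
mirsyn57	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn58	DOWN	EXPRESSION	synthetic citation	synthetic filler
mirsyn59	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn60	DOWN	EXPRESSION	synthetic citation	synthetic filler
mirsyn61	UP	EXPRESSION	synthetic citation	synthetic filler
mirsyn62	DOWN	EXPRESSION	synthetic citation	synthetic filler
mir744	UP	METHYLATION_HYPO	synthetic citation	
mirsynm01	DOWN	METHYLATION_HYPER	synthetic citation	synthetic filler
mirsynm02	UP	METHYLATION_HYPO	synthetic citation	synthetic filler
mirsynm03	DOWN	METHYLATION_HYPER	synthetic citation	synthetic filler
mirsynm04	UP	METHYLATION_HYPO	synthetic citation	synthetic filler
mirsynm05	DOWN	METHYLATION_HYPER	synthetic citation	synthetic filler
mirsynm06	UP	METHYLATION_HYPO	synthetic citation	synthetic filler
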