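cui	preferred_name
C5900001	Then (conjunction)
C5900002	The (article)
C5900003	To (preposition)
C5900004	Of (preposition)
C5900005	With (preposition)
C5900006	After (preposition)
C5900007	Her (pronoun)
C5900008	For (preposition)
C0231290	Status post
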