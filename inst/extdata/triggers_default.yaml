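# Default trigger lexicon: NegEx triggers plus sentence-level cue stems.
# The eight seeded stems (no, rule out, deny, unremarkable; risk, concern,
# worry, evaluation) are mandatory defaults; the remainder emulate a
# customized list derived from a development corpus.
negex_pre:
  - no
  - not
  - without
  - denies
  - denied
  - deny
  - no evidence of
  - no sign of
  - negative for
  - free of
  - rule out
  - ruled out
  - rules out
  - ruling out
  - rather than
  - absence of
  - never developed
  - resolution of
  - resolved
negex_post:
  - unlikely
  - was ruled out
  - is ruled out
  - has been ruled out
  - free
scope_terminators:
  - but
  - however
  - although
  - though
  - except
  - aside from
  - apart from
  - yet
  - still
  - which
  - who
  - since
sentence_negation_cues:
  - no
  - rule out
  - deny
  - unremarkable
  - without
  - negative
sentence_uncertainty_cues:
  - risk
  - concern
  - worry
  - evaluation
  - fear
  - possib
  - recommend
  - prevent
  - decreas
  - chance
  - anxious
  - goal
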