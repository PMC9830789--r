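# Illustrative Dutch ConText-style trigger lexicon.
# Columns: pattern <TAB> category <TAB> max_scope (empty = sentence scope).
# Categories: negation_forward, negation_backward, pseudo, termination.
geen	negation_forward
geen aanwijzingen voor	negation_forward
geen aanwijzing voor	negation_forward
geen tekenen van	negation_forward
geen sprake van	negation_forward
niet	negation_forward
zonder	negation_forward
nooit	negation_forward
uitgesloten	negation_backward
werd uitgesloten	negation_backward
is uitgesloten	negation_backward
afwezig	negation_backward
negatief	negation_backward
niet aangetoond	negation_backward
niet alleen	pseudo
niet uit te sluiten	pseudo
zonder twijfel	pseudo
niet zeker	pseudo
maar	termination
wel	termination
echter	termination
behalve	termination
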