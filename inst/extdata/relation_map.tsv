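relation	direction	sign	mechanism
pp	undirected	unsigned	direct
pd	forward	unsigned	indirect
INTERACTS_WITH	undirected	unsigned	direct
IN_SAME_COMPONENT	undirected	unsigned	direct
STATE_CHANGE	forward	unsigned	direct
SEQUENTIAL_CATALYSIS	forward	unsigned	indirect
METABOLIC_CATALYSIS	forward	unsigned	indirect
CO_CONTROL	undirected	unsigned	indirect
controls-state-change-of	forward	unsigned	direct
controls-phosphorylation-of	forward	unsigned	direct
controls-expression-of	forward	unsigned	indirect
controls-transport-of	forward	unsigned	direct
in-complex-with	undirected	unsigned	direct
interacts-with	undirected	unsigned	direct
catalysis-precedes	forward	unsigned	indirect
activates	forward	positive	direct
inhibits	forward	negative	direct
stimulates	forward	positive	direct
represses	forward	negative	indirect
phosphorylates	forward	positive	direct
dephosphorylates	forward	negative	direct
binds	undirected	unsigned	direct
complex	undirected	unsigned	direct
planted	forward	positive	direct
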