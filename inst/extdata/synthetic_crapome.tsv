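Gene	NumExpt
PREY01	58
PREY02	19
PREY03	7
PREY04	8
PREY05	19
PREY06	24
PREY07	54
PREY08	47
PREY09	11
PREY10	30
PREY11	36
PREY12	25
PREY13	10
PREY14	39
PREY15	5
PREY16	58
PREY17	57
PREY18	26
PREY19	5
PREY20	28
PREY21	59
PREY22	42
PREY23	56
PREY24	48
PREY25	54
PREY26	39
PREY27	44
PREY28	24
PREY29	43
PREY30	13
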