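# Biodiesel standard limits, v1. Tab-separated: set standard property min max.
# Empty min/max = unbounded on that side; a property absent from a standard
# has no designated limit. Units: iv g I2/100 g; cn dimensionless;
# density g/cm^3; kv40 mm^2/s.
# The "as-printed" set transcribes a published comparison grid whose CN and
# KV columns conflict with the official standard texts (EN CN 47 vs official
# 51; KV ranges shifted by one column); the "literature" set carries the
# official published limits.
set	standard	property	min	max
as-printed	EN14214	iv		120
as-printed	EN14214	cn	47
as-printed	EN14214	kv40	1.9	6
as-printed	ASTMD6751	cn	51
as-printed	ASTMD6751	density	0.86	0.90
as-printed	ASTMD6751	kv40	3.5	5
as-printed	IS15607	cn	51
as-printed	IS15607	density	0.86	0.89
as-printed	IS15607	kv40	2.5	6
literature	EN14214	iv		120
literature	EN14214	cn	51
literature	EN14214	density	0.86	0.90
literature	EN14214	kv40	3.5	5
literature	ASTMD6751	cn	47
literature	ASTMD6751	kv40	1.9	6
literature	IS15607	cn	51
literature	IS15607	density	0.86	0.90
literature	IS15607	kv40	2.5	6
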