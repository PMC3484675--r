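population	hom_ancestral	het	hom_derived
Africans South of the Sahara	1	6	2
Biaka Pygmy	1	2	1
Mbuti Pygmy	2	1	2
African-American	2	8	4
Druze	5	0	0
Indo-Pakistani	3	0	0
Russian Krasnodar	2	1	0
Ami	0	2	3
Chinese	1	4	0
Japanese	0	3	1
Southeast Asian	0	2	1
Pacific	3	1	0
South American	4	2	1
Mexican	4	4	0
Mexican-American	2	4	3
Puerto Rican	1	2	5
CEPH-Utah	12	10	0
Unidentified	0	1	0
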