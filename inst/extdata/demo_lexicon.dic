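%
1	negemo
2	posemo
3	anxiety
4	sadness
5	stressload
6	suicidality
7	psychotic
8	social
9	academics
10	leisure
11	work
12	health
%
antipsychotic*	7
anxi*	1	3
application	11
apprehensive	3
awesome	2
best	2
burden	1	6
burnout	5
career	11
class*	9
clinic*	12
club	8
coffee	10
cool	2
counsel*	12
course	9
cramming	5
credit	9
crying	1	4
deadline*	5
delusion*	7
depress*	1	4
derealization	7
despair*	1	4
disappear	6
doctor*	12
drained	4
dread	1	3
empty	4
episode*	7
exam*	9
exhaust*	5
finals	9
football	10
frazzled	5
friend*	8
fun	2
game	10
gloom*	1	4
good	2
goodbye	6
gpa	9
grade*	9
great	2
gym	10
hallucinat*	7
happy	2
health*	12
hopeless*	1
hotline	6
internship	11
interview*	11
jittery	3
job	11
lab	9
lecture	9
lifeline	6
lonely	1	4
love	2
miser*	1	4
movie	10
music	10
nervous	3
nice	2
numb	1
overdose	6
overwhelm*	5
panic	1	3
paranoi*	7
party	8
people	8
pressure	5
professor	9
psychosis	7
quiz	9
restless	3
resume	11
roommate	8
sad*	4
selfharm	6
semester	9
shadows	7
sick*	12
sleep*	12
social*	8
stress*	1	5
study	9
suicid*	6
swamped	5
tense	3
textbook*	9
thanks	2
therapy	12
tickets	10
unbearable	1	6
uneasy	3
unreal	7
vanish	6
visions	7
voices	7
weekend	10
workload	5
worry*	3
worthless*	1
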