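code,name,category,category_code
D1,Disease severity,Disease impact,D
D2,Size of population,Disease impact,D
C1,Clinical guidelines,Context,C
C2,Comparative interventions limitations,Context,C
I1,Improvement of efficacy/effectiveness,Intervention outcomes,I
I2,Improvement of safety & tolerability,Intervention outcomes,I
I3,Improvement of patient reported outcomes,Intervention outcomes,I
T1,Public health interest,Type of benefit,T
T2,Type of medical service,Type of benefit,T
E1,Budget impact on health plan,Economics,E
E2,Cost-effectiveness of intervention,Economics,E
E3,Impact on other spending,Economics,E
Q1,Completeness and consistency of reporting evidence,Quality of evidence,Q
Q2,Relevance and validity of evidence,Quality of evidence,Q
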