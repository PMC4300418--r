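ID,TIME,DV,AMT,II,ADDL,EVID,MDV,DROPOUT,ARM,age,sex,height,weight,bmi,severity,reversibility,pics,smoking
1,0,1.132471877749,.,.,.,0,0,0,placebo,65.6332352348524,female,159.141489563646,83.7407774672573,33.0651236540572,moderate,no,no,yes
1,28,1.281438626020,.,.,.,0,0,0,placebo,65.6332352348524,female,159.141489563646,83.7407774672573,33.0651236540572,moderate,no,no,yes
1,56,1.097403001177,.,.,.,0,0,0,placebo,65.6332352348524,female,159.141489563646,83.7407774672573,33.0651236540572,moderate,no,no,yes
1,84,1.115406401738,.,.,.,0,0,0,placebo,65.6332352348524,female,159.141489563646,83.7407774672573,33.0651236540572,moderate,no,no,yes
1,112,1.379578267968,.,.,.,0,0,0,placebo,65.6332352348524,female,159.141489563646,83.7407774672573,33.0651236540572,moderate,no,no,yes
1,140,0.973231880378,.,.,.,0,0,0,placebo,65.6332352348524,female,159.141489563646,83.7407774672573,33.0651236540572,moderate,no,no,yes
1,168,1.154014318497,.,.,.,0,0,0,placebo,65.6332352348524,female,159.141489563646,83.7407774672573,33.0651236540572,moderate,no,no,yes
1,168,.,.,.,.,3,1,0,placebo,65.6332352348524,female,159.141489563646,83.7407774672573,33.0651236540572,moderate,no,no,yes
2,0,0.534817632363,.,.,.,0,0,0,placebo,64.9761299012547,male,162.814266494622,52.2578975636317,19.7136489791788,moderate,no,no,no
2,28,0.579847922290,.,.,.,0,0,0,placebo,64.9761299012547,male,162.814266494622,52.2578975636317,19.7136489791788,moderate,no,no,no
2,56,0.733602958561,.,.,.,0,0,0,placebo,64.9761299012547,male,162.814266494622,52.2578975636317,19.7136489791788,moderate,no,no,no
2,84,0.622501370685,.,.,.,0,0,0,placebo,64.9761299012547,male,162.814266494622,52.2578975636317,19.7136489791788,moderate,no,no,no
2,112,0.858632886516,.,.,.,0,0,0,placebo,64.9761299012547,male,162.814266494622,52.2578975636317,19.7136489791788,moderate,no,no,no
2,140,0.766060430859,.,.,.,0,0,0,placebo,64.9761299012547,male,162.814266494622,52.2578975636317,19.7136489791788,moderate,no,no,no
2,168,0.565270428822,.,.,.,0,0,0,placebo,64.9761299012547,male,162.814266494622,52.2578975636317,19.7136489791788,moderate,no,no,no
2,168,.,.,.,.,3,1,0,placebo,64.9761299012547,male,162.814266494622,52.2578975636317,19.7136489791788,moderate,no,no,no
3,0,0.780557594229,.,.,.,0,0,0,salmeterol,72.512054975211,male,186.56351530123,60.6287694549475,17.419084307059,severe,no,yes,yes
3,0,.,50,12,336,1,1,0,salmeterol,72.512054975211,male,186.56351530123,60.6287694549475,17.419084307059,severe,no,yes,yes
3,28,0.857874498259,.,.,.,0,0,0,salmeterol,72.512054975211,male,186.56351530123,60.6287694549475,17.419084307059,severe,no,yes,yes
3,56,0.679289640013,.,.,.,0,0,0,salmeterol,72.512054975211,male,186.56351530123,60.6287694549475,17.419084307059,severe,no,yes,yes
3,84,0.858703540221,.,.,.,0,0,0,salmeterol,72.512054975211,male,186.56351530123,60.6287694549475,17.419084307059,severe,no,yes,yes
3,112,0.675491090405,.,.,.,0,0,0,salmeterol,72.512054975211,male,186.56351530123,60.6287694549475,17.419084307059,severe,no,yes,yes
3,140,0.520560660298,.,.,.,0,0,0,salmeterol,72.512054975211,male,186.56351530123,60.6287694549475,17.419084307059,severe,no,yes,yes
3,168,0.728430809918,.,.,.,0,0,0,salmeterol,72.512054975211,male,186.56351530123,60.6287694549475,17.419084307059,severe,no,yes,yes
3,168,.,.,.,.,3,1,0,salmeterol,72.512054975211,male,186.56351530123,60.6287694549475,17.419084307059,severe,no,yes,yes
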