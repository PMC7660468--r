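x_mm,y_mm,surface
20,0,endo
19.696,3.473,endo
18.794,6.84,endo
17.321,10,endo
15.321,12.856,endo
12.856,15.321,endo
10,17.321,endo
6.84,18.794,endo
3.473,19.696,endo
0,20,endo
-3.473,19.696,endo
-6.84,18.794,endo
-10,17.321,endo
-12.856,15.321,endo
-15.321,12.856,endo
-17.321,10,endo
-18.794,6.84,endo
-19.696,3.473,endo
-20,0,endo
-19.696,-3.473,endo
-18.794,-6.84,endo
-17.321,-10,endo
-15.321,-12.856,endo
-12.856,-15.321,endo
-10,-17.321,endo
-6.84,-18.794,endo
-3.473,-19.696,endo
-0,-20,endo
3.473,-19.696,endo
6.84,-18.794,endo
10,-17.321,endo
12.856,-15.321,endo
15.321,-12.856,endo
17.321,-10,endo
18.794,-6.84,endo
19.696,-3.473,endo
32,0,epi
31.514,5.557,epi
30.07,10.945,epi
27.713,16,epi
24.513,20.569,epi
20.569,24.513,epi
16,27.713,epi
10.945,30.07,epi
5.557,31.514,epi
0,32,epi
-5.557,31.514,epi
-10.945,30.07,epi
-16,27.713,epi
-20.569,24.513,epi
-24.513,20.569,epi
-27.713,16,epi
-30.07,10.945,epi
-31.514,5.557,epi
-32,0,epi
-31.514,-5.557,epi
-30.07,-10.945,epi
-27.713,-16,epi
-24.513,-20.569,epi
-20.569,-24.513,epi
-16,-27.713,epi
-10.945,-30.07,epi
-5.557,-31.514,epi
-0,-32,epi
5.557,-31.514,epi
10.945,-30.07,epi
16,-27.713,epi
20.569,-24.513,epi
24.513,-20.569,epi
27.713,-16,epi
30.07,-10.945,epi
31.514,-5.557,epi
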