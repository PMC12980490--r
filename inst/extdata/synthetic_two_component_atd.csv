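arrival_time_ms,intensity
4.49170092970086,0
4.51465807707032,0
4.53761522443977,0
4.56057237180923,0
4.58352951917869,0
4.60648666654815,0
4.62944381391761,0
4.65240096128707,0
4.67535810865653,0
4.69831525602599,0
4.72127240339545,0
4.74422955076491,0
4.76718669813437,0
4.79014384550383,0
4.81310099287329,0
4.83605814024275,0
4.85901528761221,0
4.88197243498167,1
4.90492958235113,0
4.92788672972058,0
4.95084387709004,0
4.97380102445950,0
4.99675817182896,3
5.01971531919842,6
5.04267246656788,8
5.06562961393734,6
5.08858676130680,12
5.11154390867626,19
5.13450105604572,31
5.15745820341518,32
5.18041535078464,52
5.20337249815410,58
5.22632964552356,84
5.24928679289302,93
5.27224394026248,122
5.29520108763194,165
5.31815823500139,213
5.34111538237085,255
5.36407252974031,328
5.38702967710977,374
5.40998682447923,444
5.43294397184869,581
5.45590111921815,705
5.47885826658761,818
5.50181541395707,916
5.52477256132653,1086
5.54772970869599,1208
5.57068685606545,1313
5.59364400343491,1504
5.61660115080437,1609
5.63955829817383,1934
5.66251544554329,1941
5.68547259291275,2190
5.70842974028220,2163
5.73138688765166,2375
5.75434403502112,2516
5.77730118239058,2445
5.80025832976004,2501
5.82321547712950,2542
5.84617262449896,2392
5.86912977186842,2342
5.89208691923788,2267
5.91504406660734,2279
5.93800121397680,2110
5.96095836134626,2047
5.98391550871572,1867
6.00687265608518,1698
6.02982980345464,1526
6.05278695082410,1422
6.07574409819355,1203
6.09870124556302,1055
6.12165839293247,935
6.14461554030193,732
6.16757268767139,664
6.19052983504085,577
6.21348698241031,479
6.23644412977977,402
6.25940127714923,326
6.28235842451869,261
6.30531557188815,216
6.32827271925761,184
6.35122986662707,187
6.37418701399653,169
6.39714416136599,129
6.42010130873545,147
6.44305845610491,155
6.46601560347437,175
6.48897275084383,157
6.51192989821328,198
6.53488704558274,258
6.55784419295220,329
6.58080134032166,343
6.60375848769112,360
6.62671563506058,415
6.64967278243004,466
6.67262992979950,603
6.69558707716896,710
6.71854422453842,751
6.74150137190788,860
6.76445851927734,931
6.78741566664680,990
6.81037281401626,1182
6.83332996138572,1249
6.85628710875518,1349
6.87924425612464,1448
6.90220140349409,1655
6.92515855086355,1701
6.94811569823301,1925
6.97107284560247,1965
6.99402999297193,2167
7.01698714034139,2212
7.03994428771085,2274
7.06290143508031,2452
7.08585858244977,2372
7.10881572981923,2463
7.13177287718869,2633
7.15473002455815,2672
7.17768717192761,2604
7.20064431929707,2618
7.22360146666653,2647
7.24655861403599,2610
7.26951576140544,2661
7.29247290877490,2599
7.31543005614436,2488
7.33838720351382,2421
7.36134435088328,2305
7.38430149825274,2307
7.40725864562220,2178
7.43021579299166,2095
7.45317294036112,1980
7.47613008773058,1841
7.49908723510004,1772
7.52204438246950,1645
7.54500152983896,1562
7.56795867720842,1380
7.59091582457788,1289
7.61387297194734,1181
7.63683011931680,999
7.65978726668625,949
7.68274441405572,796
7.70570156142517,813
7.72865870879463,647
7.75161585616409,561
7.77457300353355,468
7.79753015090301,440
7.82048729827247,381
7.84344444564193,356
7.86640159301139,274
7.88935874038085,270
7.91231588775031,210
7.93527303511977,171
7.95823018248923,158
7.98118732985869,133
8.00414447722815,100
8.02710162459761,93
8.05005877196707,64
8.07301591933652,56
8.09597306670598,51
8.11893021407544,42
8.14188736144490,29
8.16484450881436,25
8.18780165618382,16
8.21075880355328,16
8.23371595092274,11
8.25667309829220,10
8.27963024566166,9
8.30258739303112,4
8.32554454040058,4
8.34850168777004,2
8.37145883513950,3
8.39441598250896,3
8.41737312987842,3
8.44033027724788,2
8.46328742461733,0
8.48624457198679,0
8.50920171935625,0
8.53215886672571,0
8.55511601409517,0
8.57807316146463,0
8.60103030883409,0
8.62398745620355,0
8.64694460357301,0
8.66990175094247,0
8.69285889831193,0
8.71581604568139,0
8.73877319305085,0
8.76173034042031,0
8.78468748778977,0
8.80764463515923,0
8.83060178252869,0
8.85355892989815,0
8.87651607726760,0
8.89947322463706,0
8.92243037200652,0
8.94538751937598,0
8.96834466674544,0
8.99130181411490,0
9.01425896148436,0
9.03721610885382,0
9.06017325622328,0
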