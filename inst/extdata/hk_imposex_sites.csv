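"site_id","site_name","epoch","mean_vdsi","median_vdsi","pct_imposex","pct_sterile","rpsi","condition_index","distance_km"
1,"Kat O","2004-06",3.92,4,100,0,1.59,,2.7
2,"Pak Sha Chau","2004-06",3.57,4,100,0,0.37,,4.9
3,"Chek Chau","2004-06",3.5,3.5,100,0,0.57,,10.3
4,"Wu Kwai Sha","2004-06",2.67,3,100,0,0.17,,4.3
5,"Heng On","2004-06",3.64,4,100,0,0.84,,18.5
6,"Wong Mau Chau","2004-06",3.03,3,100,0,0.11,,17
7,"Kong Tau Pai","2004-06",2.38,2,100,0,0.06,,11.4
8,"Sai Kung Pier","2004-06",4.7,4,100,40,34.38,,0.2
9,"UST","2004-06",4.17,4,100,11.1,8.85,,2.9
10,"Clear Water Bay","2004-06",3.04,3,100,0,0.53,,8.9
11,"Shek Mei Tao","2004-06",3.22,3,100,0,0.15,,5.8
12,"Tung Lung Island","2004-06",4,4,100,0,12.59,,5.4
13,"Waglan Island","2004-06",3,3,100,0,0.18,,11.5
14,"Po Toi","2004-06",3.52,4,100,0,2.32,,11.9
15,"Shek O","2004-06",3.9,4,100,5,29.65,,4.8
16,"Turtle Cove","2004-06",3.33,3,100,0,0.43,,6.4
17,"Chung Hum Kok","2004-06",4.1,4,100,4.8,9.01,,4.7
18,"Repulse Bay","2004-06",3.9,4,100,10.5,11.84,,3.7
19,"Deep Water Bay","2004-06",4.35,4,100,29.4,7.72,,2.5
20,"Aberdeen","2004-06",5,5,100,83.3,64.22,,1.4
21,"Sok Kwu Wan","2004-06",5.36,6,100,71.4,12.07,,0.4
22,"Ha Mei Wan","2004-06",3.65,4,100,0,1.89,,2.9
23,"Mui Wo","2004-06",4,4,100,0,3.05,,0.8
24,"Cheung Sha","2004-06",4,4,100,0,1.26,,6.2
25,"Tai O","2004-06",3.79,4,100,0,3.18,,0.2
26,"Butterfly Beach","2004-06",4.11,4,100,33.3,15.56,,1.7
27,"Kadoorie Beach","2004-06",4.87,5,100,53.3,38.43,,0.9
28,"Pak Sha Wan","2004-06",4.46,,100,25,60.61,,0
29,"Waterfall Bay","2004-06",4.06,,100,6.3,59.8,,1.5
1,"Kat O","2010",4.08,4,100,24,9.33,16.6,2.7
2,"Pak Sha Chau","2010",3.14,3,100,0,8.14,18.7,4.9
3,"Chek Chau","2010",3.1,3,100,0,4.74,18.3,10.3
4,"Wu Kwai Sha","2010",3.56,3.5,100,22.2,6,24.4,4.3
5,"Heng On","2010",,,,,,,18.5
6,"Wong Mau Chau","2010",3.09,3,100,18.2,4.17,15.8,17
7,"Kong Tau Pai","2010",2.69,3,100,0,6.36,19,11.4
8,"Sai Kung Pier","2010",4.94,5,100,72.2,94.66,20.5,0.2
9,"UST","2010",4.55,4,100,45,48.6,21.6,2.9
10,"Clear Water Bay","2010",2.81,2,100,9.5,1.71,19.3,8.9
11,"Shek Mei Tao","2010",3.33,3,100,12.5,3.32,19.4,5.8
12,"Tung Lung Island","2010",3.92,4,100,16,13.06,18.9,5.4
13,"Waglan Island","2010",2.61,3,100,0,1.19,20,11.5
14,"Po Toi","2010",2.76,3,100,5.9,2.19,18.6,11.9
15,"Shek O","2010",4.53,5,100,52.9,18.09,22.5,4.8
16,"Turtle Cove","2010",3.3,3,100,10,3.96,21.7,6.4
17,"Chung Hum Kok","2010",4.56,4.5,100,50,10.82,25.1,4.7
18,"Repulse Bay","2010",3.97,4,100,26.7,11.02,24.8,3.7
19,"Deep Water Bay","2010",3.45,3,100,25,7.1,15.2,2.5
20,"Aberdeen","2010",5.05,5,100,71.4,26.05,22.8,1.4
21,"Sok Kwu Wan","2010",5.73,6,100,93.3,37.7,23.8,0.4
22,"Ha Mei Wan","2010",4.41,4,100,40.7,16.72,25.6,2.9
23,"Mui Wo","2010",3.05,3,100,5.3,8.76,29,0.8
24,"Cheung Sha","2010",3.79,3,100,26.3,13.73,16.8,6.2
25,"Tai O","2010",4.17,4,100,39.1,24.8,20,0.2
26,"Butterfly Beach","2010",3.96,4,100,21.7,34.4,26.8,1.7
27,"Kadoorie Beach","2010",4,4,100,28.6,21.21,28.9,0.9
28,"Pak Sha Wan","2010",4.79,5,100,57.9,46.58,24.4,0
29,"Waterfall Bay","2010",4.87,5,100,53.3,11.56,26.1,1.5
1,"Kat O","2015",,,,,,,2.7
2,"Pak Sha Chau","2015",,,,,,,4.9
3,"Chek Chau","2015",,,,,,,10.3
4,"Wu Kwai Sha","2015",,,,,,,4.3
5,"Heng On","2015",,,,,,,18.5
6,"Wong Mau Chau","2015",,,,,,,17
7,"Kong Tau Pai","2015",,,,,,,11.4
8,"Sai Kung Pier","2015",4.78,5,100,55.6,48,20.3,0.2
9,"UST","2015",,,,,,,2.9
10,"Clear Water Bay","2015",4.71,5,100,52.9,31.7,22.4,8.9
11,"Shek Mei Tao","2015",,,,,,,5.8
12,"Tung Lung Island","2015",,,,,,,5.4
13,"Waglan Island","2015",,,,,,,11.5
14,"Po Toi","2015",3.61,3,100,13,9.61,18.6,11.9
15,"Shek O","2015",4.4,4,100,35,21.55,16.8,4.8
16,"Turtle Cove","2015",3.74,4,100,15.8,8.05,19.6,6.4
17,"Chung Hum Kok","2015",,,,,,,4.7
18,"Repulse Bay","2015",,,,,,,3.7
19,"Deep Water Bay","2015",4.9,5,100,57.1,33.12,21.9,2.5
20,"Aberdeen","2015",5.21,5,100,91.7,42.96,24.9,1.4
21,"Sok Kwu Wan","2015",5.22,5,100,94.4,38.87,24.5,0.4
22,"Ha Mei Wan","2015",,,,,,,2.9
23,"Mui Wo","2015",,,,,,,0.8
24,"Cheung Sha","2015",,,,,,,6.2
25,"Tai O","2015",,,,,,,0.2
26,"Butterfly Beach","2015",4.95,5,100,60,46.19,27.4,1.7
27,"Kadoorie Beach","2015",4.47,5,100,52.9,43.6,25.4,0.9
28,"Pak Sha Wan","2015",,,,,,,0
29,"Waterfall Bay","2015",,,,,,,1.5
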