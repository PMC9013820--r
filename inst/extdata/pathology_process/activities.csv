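"id","description","category","table7_hours","mean_min","sd_min","resource","placeholder","successor"
1,"Receive the tissue specimen","operation",NA,0.5,0,"cutting_technician",TRUE,2
2,"Await check-in of the request","queue",NA,0.5,0,NA,TRUE,3
3,"Check the biopsy request card data","inspection",2.336,0.586443514644351,0,"cutting_technician",FALSE,4
4,"Number the biopsy consecutively","operation",5.274,1.32401673640167,0,"cutting_technician",FALSE,5
5,"Enter data into the SIPAT software","operation",6.573,1.65012552301255,0,"cutting_technician",FALSE,6
6,"Hold the specimen before cutting","storage",NA,0.5,0,NA,TRUE,7
7,"Prepare formalin jars for the specimens","operation",1.46,0.36652719665272,0,"cutting_technician",FALSE,8
8,"Cut the specimens","operation",4.621,1.16008368200837,0,"pathologist",FALSE,9
9,"Enter the data into the SIPAT software","operation",6.575,1.65062761506276,0,"cutting_technician",FALSE,10
10,"Fix the specimens in formalin jars","operation",1.997,0.501338912133891,0,"cutting_technician",FALSE,11
11,"Send the specimens to histology","transport",1.597,0.40092050209205,0,NA,FALSE,12
12,"Check the received specimens' information","inspection",2.34,0.58744769874477,0,"histology_technician",FALSE,13
13,"Centrifuge the jar contents","operation",19.975,5.01464435146443,0,"histology_technician",FALSE,14
14,"Clean the embedder","operation",0.399,0.100167364016736,0,"histology_technician",FALSE,15
15,"Translate the specimens","transport",1.596,0.400669456066946,0,NA,FALSE,16
16,"Put the specimens in the containers","storage",0.399,0.100167364016736,0,NA,FALSE,17
17,"Pedal-controlled paraffin-filling of the containers","operation",0.799,0.200585774058577,0,"histology_technician",FALSE,18
18,"Cool the paraffin wax","operation",0.399,0.100167364016736,0,"histology_technician",FALSE,19
19,"Store sample blocks in refrigerator","storage",39.912,10.0197489539749,0,NA,FALSE,20
20,"Clean microtome","operation",0.399,0.100167364016736,0,"histology_technician",FALSE,21
21,"Put blade in microtome","operation",0.399,0.100167364016736,0,"histology_technician",FALSE,22
22,"Translate the sample blocks to the microtome","transport",1.596,0.400669456066946,0,NA,FALSE,23
23,"Put sample block in microtome","operation",0.399,0.100167364016736,0,"histology_technician",FALSE,24
24,"Preliminary trim of the block","operation",3.021,0.758410041841004,0,"histology_technician",FALSE,25
25,"Manual slicing","operation",8.543,2.14468619246862,0,"histology_technician",FALSE,26
26,"Pass specimens to the bain marie","operation",0.399,0.100167364016736,0,"histology_technician",FALSE,27
27,"Place tissue sample on the slide","operation",0.399,0.100167364016736,0,"histology_technician",FALSE,28
28,"Number and dry the slide","operation",19.968,5.0128870292887,0,"histology_technician",FALSE,29
29,"Place slides in basket","storage",0.799,0.200585774058577,0,NA,FALSE,30
30,"Bring the basket over to the staining area","transport",1.595,0.400418410041841,0,NA,FALSE,31
31,"Staining of the slides in the basket","operation",4.488,1.12669456066946,0,"histology_technician",FALSE,32
32,"Storage of the slides","storage",37.482,9.40970711297071,0,NA,FALSE,33
33,"The pathologist goes to the slide storage area","transport",36.95,9.27615062761506,0,NA,FALSE,34
34,"The pathologist examines the slides","operation",6.569,1.64912133891213,0,"pathologist",FALSE,35
35,"Prepare the diagnosis report","operation",NA,0.5,0,"pathologist",TRUE,36
36,"Deliver the report","transport",NA,0.5,0,NA,TRUE,NA
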