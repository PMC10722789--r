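session_id,actor,onset_s,offset_s,code
example-01,child,1.7459510709364148,2.951705256879362,bid
example-01,caregiver,1.9517052568793618,2.951705256879362,respond
example-01,caregiver,2.951705256879362,18.999836966966782,engage
example-01,child,2.951705256879362,18.999836966966782,engage
example-01,child,20.510037923425703,22.12075998651246,bid
example-01,caregiver,21.12075998651246,22.12075998651246,respond
example-01,caregiver,22.12075998651246,48.52857426675662,engage
example-01,child,22.12075998651246,48.52857426675662,engage
example-01,child,52.16756827229075,55.211893976622015,bid
example-01,caregiver,54.211893976622015,55.211893976622015,respond
example-01,caregiver,55.211893976622015,66.76671290728162,engage
example-01,child,55.211893976622015,66.76671290728162,engage
example-01,child,72.3109635803882,73.44386164502731,bid
example-01,caregiver,72.44386164502731,73.44386164502731,respond
example-01,caregiver,73.44386164502731,85.4392858631906,engage
example-01,child,73.44386164502731,85.4392858631906,engage
example-01,caregiver,85.54592465975051,88.06653405054719,bid
example-01,child,87.06653405054719,88.06653405054719,respond
example-01,caregiver,88.06653405054719,95.94629417579527,engage
example-01,child,88.06653405054719,95.94629417579527,engage
example-01,child,96.48083522304314,99.48083522304314,bid
example-01,child,103.99394586645101,106.99394586645101,bid
example-01,child,115.77888804938493,117.75817505460309,bid
example-01,caregiver,116.75817505460309,117.75817505460309,respond
example-01,caregiver,117.75817505460309,119.6699352838898,engage
example-01,child,117.75817505460309,119.6699352838898,engage
example-01,child,122.09776958538747,125.09776958538747,bid
example-01,child,135.60732452956927,137.93015749952258,bid
example-01,caregiver,136.93015749952258,137.93015749952258,respond
example-01,caregiver,137.93015749952258,147.96258586213474,engage
example-01,child,137.93015749952258,147.96258586213474,engage
example-01,child,148.58506015507632,149.7782554658117,bid
example-01,caregiver,148.7782554658117,149.7782554658117,respond
example-01,caregiver,149.7782554658117,150.3080623111688,engage
example-01,child,149.7782554658117,150.3080623111688,engage
example-01,child,154.43824501518338,157.43824501518338,bid
example-01,child,159.05403425396412,160.78967030308326,bid
example-01,caregiver,159.78967030308326,160.78967030308326,respond
example-01,caregiver,160.78967030308326,162.82633976433797,engage
example-01,child,160.78967030308326,162.82633976433797,engage
example-01,child,172.93440920040877,175.39336600707392,bid
example-01,caregiver,174.39336600707392,175.39336600707392,respond
example-01,caregiver,175.39336600707392,180,engage
example-01,child,175.39336600707392,180,engage
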