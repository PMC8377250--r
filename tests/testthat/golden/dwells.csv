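# socialgaze config_md5=8ef22bf32e94caa5c22a038259694af5 seed=20260101
aoi,onset,offset,duration,n_fixations,participant,block,instructed
A,0,2325,2325,1,p01,1,RJA
O1,2358.33,3475,1116.67,1,p01,1,RJA
A,3491.67,4841.67,1350,1,p01,1,RJA
O3,4858.33,5858.33,1000,2,p01,1,RJA
A,5875,7258.33,1383.33,1,p01,1,RJA
O1,7275,7991.67,716.67,1,p01,1,RJA
A,0,425,425,1,p01,2,OO
O2,441.67,2291.67,1850,1,p01,2,OO
O3,2325,3175,850,1,p01,2,OO
O4,3191.67,4058.33,866.67,1,p01,2,OO
O3,4075,5541.67,1466.67,1,p01,2,OO
A,5575,6591.67,1016.67,1,p01,2,OO
O1,6608.33,7875,1266.67,1,p01,2,OO
O2,7908.33,7991.67,83.33,1,p01,2,OO
O1,0,408.33,408.33,1,p01,3,PO
A,441.67,1625,1183.33,1,p01,3,PO
O4,1641.67,1958.33,316.67,1,p01,3,PO
A,1975,5491.67,3516.67,1,p01,3,PO
O4,5508.33,5725,216.67,1,p01,3,PO
A,5758.33,7141.67,1383.33,1,p01,3,PO
O1,7158.33,7425,266.67,1,p01,3,PO
A,7458.33,7991.67,533.33,1,p01,3,PO
O4,0,508.33,508.33,1,p01,4,INT
A,0,875,875,1,p01,5,IJA
O4,908.33,1725,816.67,1,p01,5,IJA
A,1741.67,2658.33,916.67,1,p01,5,IJA
O4,2675,3508.33,833.33,1,p01,5,IJA
O3,3525,4408.33,883.33,1,p01,5,IJA
A,4425,5291.67,866.67,1,p01,5,IJA
O1,5325,6308.33,983.33,1,p01,5,IJA
A,6341.67,7208.33,866.67,1,p01,5,IJA
O1,7225,7991.67,766.67,1,p01,5,IJA
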