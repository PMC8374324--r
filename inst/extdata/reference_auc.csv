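model,subset,best_auc,best_beta,worst_auc,worst_beta
BVAE,a,0.825,0.01,0.798,1
BVAE,b,0.559,1,0.551,0.1
BVAE,d,0.691,100,0.583,0.1
BVAE,e,0.923,0.01,0.881,1
BVAE,f,0.846,100,0.801,10
BVAE,ae,0.822,0.01,0.765,100
BVAE,ef,0.899,0.01,0.836,10
BVAE,ALL,0.786,0.01,0.644,100
BVAE,Michigan,0.966,1,0.725,0.1
DBVAE,a,0.862,0.1,0.763,100
DBVAE,b,0.642,0.01,0.523,0.1
DBVAE,d,0.845,0.1,0.726,100
DBVAE,e,0.924,0.01,0.844,100
DBVAE,f,0.831,10,0.787,1
DBVAE,ae,0.861,0.01,0.793,100
DBVAE,ef,0.914,0.01,0.870,100
DBVAE,ALL,0.803,0.01,0.719,10
DBVAE,Michigan,0.966,1,0.731,0.1
DBAE,a,0.842,0.1,0.762,10
DBAE,b,0.614,1,0.527,100
DBAE,d,0.940,0.1,0.750,0.01
DBAE,e,0.928,0.1,0.918,1
DBAE,f,0.842,10,0.765,100
DBAE,ae,0.887,0.1,0.851,10
DBAE,ef,0.929,100,0.895,10
DBAE,ALL,0.808,1,0.761,100
DBAE,Michigan,0.944,0.01,0.616,1
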