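image_id,image_type,mse,psnr_db,cc,ssim,bpp,time_ms
MRI-1,Brain,0.683,39.82,0.9978,0.9721,3.05,652.0
MRI-2,Brain,0.728,38.91,0.9969,0.9664,3.22,684.0
MRI-3,Brain,0.591,41.45,0.9985,0.9782,2.98,611.0
MRI-4,Brain,0.705,39.21,0.9973,0.9706,3.10,663.0
CT-1,Thorax,0.476,42.08,0.9987,0.9769,2.61,598.0
CT-2,Head,0.522,41.30,0.9979,0.9735,2.72,604.0
CT-3,Lung,0.613,40.16,0.9971,0.9693,2.85,622.0
CT-4,Abdomen,0.589,40.50,0.9968,0.9650,2.76,647.0
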