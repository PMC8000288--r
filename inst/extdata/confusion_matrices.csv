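model,architecture,method,tn,fp,fn,tp
ResNet_Nearest,ResNet,nearest,19,33,3,49
ResNet_Bilinear,ResNet,bilinear,26,26,2,50
ResNet_Bicubic,ResNet,bicubic,38,14,13,39
ResNet_Lanczos,ResNet,lanczos,49,3,27,25
ResNet_SRCNN,ResNet,srcnn,33,19,5,47
ResNet_SRGAN,ResNet,srgan,46,6,21,31
Inception_Nearest,Inception,nearest,32,20,2,50
Inception_Bilinear,Inception,bilinear,25,27,5,74
Inception_Bicubic,Inception,bicubic,37,15,4,48
Inception_Lanczos,Inception,lanczos,25,27,1,51
Inception_SRCNN,Inception,srcnn,32,20,9,43
Inception_SRGAN,Inception,srgan,36,16,10,42
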