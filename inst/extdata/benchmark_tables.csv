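table,horizon,metric,model,value
comparison,24,MAE,ns_Transformer,4.956
comparison,24,MAE,Informer,5.282
comparison,24,MAE,Autoformer,5.206
comparison,24,MAE,Reformer,4.960
comparison,24,MAE,Pyraformer,5.092
comparison,24,MAE,LightTS,4.616
comparison,24,MAE,ConvFormer,4.595
comparison,24,RMSE,ns_Transformer,8.075
comparison,24,RMSE,Informer,8.450
comparison,24,RMSE,Autoformer,8.664
comparison,24,RMSE,Reformer,7.817
comparison,24,RMSE,Pyraformer,8.120
comparison,24,RMSE,LightTS,7.516
comparison,24,RMSE,ConvFormer,7.463
comparison,24,R2,ns_Transformer,0.603
comparison,24,R2,Informer,0.566
comparison,24,R2,Autoformer,0.544
comparison,24,R2,Reformer,0.628
comparison,24,R2,Pyraformer,0.599
comparison,24,R2,LightTS,0.656
comparison,24,R2,ConvFormer,0.661
comparison,48,MAE,ns_Transformer,6.432
comparison,48,MAE,Informer,7.436
comparison,48,MAE,Autoformer,6.333
comparison,48,MAE,Reformer,6.179
comparison,48,MAE,Pyraformer,5.700
comparison,48,MAE,LightTS,5.856
comparison,48,MAE,ConvFormer,5.799
comparison,48,RMSE,ns_Transformer,10.648
comparison,48,RMSE,Informer,10.778
comparison,48,RMSE,Autoformer,10.001
comparison,48,RMSE,Reformer,9.549
comparison,48,RMSE,Pyraformer,8.879
comparison,48,RMSE,LightTS,9.134
comparison,48,RMSE,ConvFormer,8.760
comparison,48,R2,ns_Transformer,0.352
comparison,48,R2,Informer,0.336
comparison,48,R2,Autoformer,0.428
comparison,48,R2,Reformer,0.479
comparison,48,R2,Pyraformer,0.549
comparison,48,R2,LightTS,0.523
comparison,48,R2,ConvFormer,0.561
comparison,96,MAE,ns_Transformer,7.237
comparison,96,MAE,Informer,6.749
comparison,96,MAE,Autoformer,7.359
comparison,96,MAE,Reformer,6.390
comparison,96,MAE,Pyraformer,6.146
comparison,96,MAE,LightTS,6.170
comparison,96,MAE,ConvFormer,6.132
comparison,96,RMSE,ns_Transformer,11.179
comparison,96,RMSE,Informer,10.443
comparison,96,RMSE,Autoformer,11.417
comparison,96,RMSE,Reformer,10.489
comparison,96,RMSE,Pyraformer,9.458
comparison,96,RMSE,LightTS,9.845
comparison,96,RMSE,ConvFormer,9.516
comparison,96,R2,ns_Transformer,0.232
comparison,96,R2,Informer,0.331
comparison,96,R2,Autoformer,0.198
comparison,96,R2,Reformer,0.324
comparison,96,R2,Pyraformer,0.442
comparison,96,R2,LightTS,0.405
comparison,96,R2,ConvFormer,0.444
ablation,24,R2,CNN,0.647
ablation,24,R2,Transformer,0.635
ablation,24,R2,ConvFormer,0.661
ablation,48,R2,CNN,0.536
ablation,48,R2,Transformer,0.485
ablation,48,R2,ConvFormer,0.561
ablation,96,R2,CNN,0.405
ablation,96,R2,Transformer,0.350
ablation,96,R2,ConvFormer,0.444
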