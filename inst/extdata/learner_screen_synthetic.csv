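learner,rmse_train,rmse_val
regr.rfsrc,1.05,1.21
regr.glmboost,1.10,1.28
regr.lightgbm,1.02,1.25
regr.kknn,1.08,1.22
regr.earth,0.55,0.68
regr.lm,1.85,2.41
regr.ranger,0.48,1.52
regr.randomForest,0.52,1.58
regr.svm,0.88,1.74
regr.ksvm,0.91,1.69
regr.xgboost,0.10,3.20
regr.gbm,0.21,2.75
regr.catboost,0.35,2.10
regr.glmnet,1.62,2.05
regr.cv_glmnet,1.58,1.98
regr.nnet,2.90,3.65
regr.rpart,1.45,2.32
regr.ctree,1.52,2.44
regr.cforest,1.20,1.77
regr.km,0.95,85.42
regr.gausspr,1.15,2.60
regr.kernlab,1.32,2.21
regr.ibk,1.75,2.38
regr.m5rules,1.40,1.95
regr.cubist,0.30,1.85
regr.bart,0.62,1.66
regr.mob,1.98,2.66
regr.fnn,2.05,2.84
regr.gam,1.36,1.92
regr.mars,1.28,1.90
regr.featureless,4.02,4.30
regr.debug_mean,3.60,3.95
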