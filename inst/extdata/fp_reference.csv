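fp,channel,reference_fp,relative_brightness,half_life_s
EGFP,green,EGFP,1.0,23
mStayGold,green,EGFP,3.0,60
mBaoJin,green,EGFP,NA,20
mCherry,red,mCherry,1.0,21
mScarlet-I,red,mCherry,1.6,5.4
mScarlet3,red,mCherry,1.9,6.5
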