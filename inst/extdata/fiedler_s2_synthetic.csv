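dataset_id,covariate_level,dose,response,subject_id
fiedler_synthetic,male,0,1.64057221321207,male_0_01
fiedler_synthetic,male,0,2.11958496591308,male_0_02
fiedler_synthetic,male,0,1.53556472320962,male_0_03
fiedler_synthetic,male,0,3.31222200505892,male_0_04
fiedler_synthetic,male,0,2.21964369915296,male_0_05
fiedler_synthetic,male,14.3,1.77438562941271,male_14.3_01
fiedler_synthetic,male,14.3,2.68330092024141,male_14.3_02
fiedler_synthetic,male,14.3,2.90486783924493,male_14.3_03
fiedler_synthetic,male,14.3,2.75932800458075,male_14.3_04
fiedler_synthetic,male,14.3,2.08827180320481,male_14.3_05
fiedler_synthetic,male,28.5,4.38530882418954,male_28.5_01
fiedler_synthetic,male,28.5,3.07551425567933,male_28.5_02
fiedler_synthetic,male,28.5,2.23387857994259,male_28.5_03
fiedler_synthetic,male,28.5,1.34964726271079,male_28.5_04
fiedler_synthetic,male,28.5,3.8803573903789,male_28.5_05
fiedler_synthetic,male,57,3.53703692320232,male_57_01
fiedler_synthetic,male,57,3.56933317762359,male_57_02
fiedler_synthetic,male,57,4.83540950114049,male_57_03
fiedler_synthetic,male,57,4.65150837178536,male_57_04
fiedler_synthetic,male,57,4.32887066734227,male_57_05
fiedler_synthetic,male,114,6.5524653383158,male_114_01
fiedler_synthetic,male,114,6.27496821845793,male_114_02
fiedler_synthetic,male,114,5.01691259321839,male_114_03
fiedler_synthetic,male,114,2.61208032310223,male_114_04
fiedler_synthetic,male,114,5.96101826724574,male_114_05
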