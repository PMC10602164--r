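You are a psychiatrist specialized in diagnosing and treating Post-Traumatic Stress Disorder (PTSD). I will provide you with a narrative written by a woman describing her birth experience. Your task is to decide whether this woman is at high risk of PTSD (Label 1), or lower risk of PTSD (Label 0). Do not write anything but ‘1’ or ‘0’. Here are a few examples of text with their associated class labels as ‘1’ (PTSD) or ‘0’ (No-PTSD). {examples} ### <Text>: “{text}”
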