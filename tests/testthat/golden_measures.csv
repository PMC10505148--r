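"participant_id","task","modality","measure","raw","log","n_tokens","missing_reason","mean_rate"
"CHR001","AMR","remote","voiceless_vot_cov","0.3887526986","-0.9448118737","24","","4.704248697"
"CHR001","AMR","remote","speech_rate_cov","0.06202301142","-2.780249811","12","","4.704248697"
"CHR001","AMR","remote","vowel_duration_cov","0.1487644693","-1.905390967","48","","4.704248697"
"CHR001","AMR","remote","formant_dispersion_20","","","0","no_formants","4.704248697"
"CHR001","AMR","remote","formant_dispersion_change_20_50","","","48","no_formants","4.704248697"
"CHR001","AMR","remote","syllable_duration_cov","0.1247592737","-2.081369208","48","","4.704248697"
"CHR001","AMR","remote","intersyllable_duration_cov","0.2451115258","-1.406041965","36","","4.704248697"
"CHR001","READ","remote","voiceless_vot_cov","0.4456537312","-0.808213016","3","","4.143869616"
"CHR001","READ","remote","voiced_vot_cov","0.387240514","-0.9487092957","5","","4.143869616"
"CHR001","READ","remote","speech_rate_cov","0.2235157632","-1.498273339","5","","4.143869616"
"CHR001","READ","remote","vowel_duration_cov","0.5484749604","-0.6006136513","16","","4.143869616"
"CHR001","READ","remote","formant_dispersion_20","","","0","no_formants","4.143869616"
"CHR001","READ","remote","formant_dispersion_change_20_50","","","16","no_formants","4.143869616"
"CHR001","READ","remote","vowel_category_overlap","","","16","one_category","4.143869616"
"CHR001","READ","remote","pause_rate","0.29238124","-1.229696712","","","4.143869616"
"HC001","AMR","in_person","voiceless_vot_cov","0.1493798304","-1.90126302","24","","4.48813497"
"HC001","AMR","in_person","speech_rate_cov","0.02840978924","-3.561021501","12","","4.48813497"
"HC001","AMR","in_person","vowel_duration_cov","0.1679760554","-1.783933837","48","","4.48813497"
"HC001","AMR","in_person","formant_dispersion_20","","","0","no_formants","4.48813497"
"HC001","AMR","in_person","formant_dispersion_change_20_50","","","48","no_formants","4.48813497"
"HC001","AMR","in_person","syllable_duration_cov","0.09989070643","-2.303678626","48","","4.48813497"
"HC001","AMR","in_person","intersyllable_duration_cov","0.212838331","-1.547222411","36","","4.48813497"
"HC001","READ","in_person","voiceless_vot_cov","","","1","insufficient_tokens","4.884071289"
"HC001","READ","in_person","voiced_vot_cov","0.3868948865","-0.9496022339","3","","4.884071289"
"HC001","READ","in_person","speech_rate_cov","0.1947656765","-1.635958102","5","","4.884071289"
"HC001","READ","in_person","vowel_duration_cov","0.5397681389","-0.6166156041","25","","4.884071289"
"HC001","READ","in_person","formant_dispersion_20","","","0","no_formants","4.884071289"
"HC001","READ","in_person","formant_dispersion_change_20_50","","","25","no_formants","4.884071289"
"HC001","READ","in_person","vowel_category_overlap","","","25","one_category","4.884071289"
"HC001","READ","in_person","pause_rate","0.3335787365","-1.09787635","","","4.884071289"
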