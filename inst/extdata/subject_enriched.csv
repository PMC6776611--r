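"Document Information","author","","date","","version","","repository","","","",""
"Path to Section","Section Name","Section Type","Section Definition","Property Name","Property Definition","Value","Data Unit","Data Uncertainty","odML Data Type","Value Origin","Property Reference"
"/Subject/Scores_2000-01-01","Scores_2000-01-01","scores","","Date","","2000-01-01","","","date","",""
"/Subject/Scores_2000-01-01","Scores_2000-01-01","scores","","Weight","","5.0","g","","float","",""
"/Subject/Scores_2000-01-01","Scores_2000-01-01","scores","","Experimenter","","Alice","","","string","",""
"/Subject/Scores_2000-01-01","Scores_2000-01-01","scores","","Comment","","Blood sample was taken [...]","","","text","",""
"/Subject/Scores_2000-01-02","Scores_2000-01-02","scores","","Date","","2000-01-02","","","date","",""
"/Subject/Scores_2000-01-02","Scores_2000-01-02","scores","","Weight","","5.5","g","","float","",""
"/Subject/Scores_2000-01-02","Scores_2000-01-02","scores","","Experimenter","","Bob","","","string","",""
"/Subject/Scores_2000-01-02","Scores_2000-01-02","scores","","Comment","","Small scratch at the right ear","","","text","",""
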