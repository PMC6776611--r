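"Document Information","author","","date","","version","","repository",""
"Section","Measure","Value","Unit","Type","","","",""
"/Subject/Scores_YYYY-MM-DD","Date","","","date","","","",""
"/Subject/Scores_YYYY-MM-DD","Weight","","g","float","","","",""
"/Subject/Scores_YYYY-MM-DD","Experimenter","Alice","","string","","","",""
"/Subject/Scores_YYYY-MM-DD","Comment","","","text","","","",""
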