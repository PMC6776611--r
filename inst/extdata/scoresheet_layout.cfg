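compaction=false
column=path_to_section=Section
column=property_name=Measure
column=value=Value
column=data_unit=Unit
column=odml_data_type=Type
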