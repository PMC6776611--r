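<?xml version="1.0" encoding="UTF-8"?>
<odML version="1.3">
  <author>Alice</author>
  <section>
    <name>Subject</name>
    <type>subject</type>
    <section>
      <name>Scores_2000-01-01</name>
      <type>scores</type>
      <property>
        <name>Date</name>
        <value>2000-01-01<type>date</type></value>
      </property>
      <property>
        <name>Weight</name>
        <value>5.0<unit>g</unit><type>float</type></value>
        <value>5.5<unit>g</unit></value>
      </property>
      <property>
        <name>Experimenter</name>
        <value>Alice<type>string</type></value>
      </property>
    </section>
  </section>
</odML>
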