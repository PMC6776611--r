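<?xml version="1.0" encoding="UTF-8"?>
<odML version="1.4">
  <section>
    <name>Subject</name>
    <type>subject</type>
    <id>02b7baf9-5e38-4646-b52e-160003ff532e</id>
    <section>
      <name>Scores_2000-01-01</name>
      <type>scores</type>
      <id>20556d0f-83d5-4439-9f6a-db2c056c1d75</id>
      <property>
        <name>Date</name>
        <type>date</type>
        <id>88add0c2-df00-4278-978b-8e0844a3231f</id>
        <value>2000-01-01</value>
      </property>
      <property>
        <name>Weight</name>
        <type>float</type>
        <unit>g</unit>
        <id>66f9156d-4ac3-4884-8739-5967adaf4ee8</id>
        <value>5.0</value>
      </property>
      <property>
        <name>Experimenter</name>
        <type>string</type>
        <id>d3d16078-7d24-418e-a57c-098fa5ab84ee</id>
        <value>Alice</value>
      </property>
      <property>
        <name>Comment</name>
        <type>text</type>
        <id>eba9398b-79d7-44e9-8fcc-3556a2dd1db9</id>
        <value>Blood sample was taken [...]</value>
      </property>
    </section>
    <section>
      <name>Scores_2000-01-02</name>
      <type>scores</type>
      <id>bce42fbf-6e7f-4024-8195-535a3cc85a71</id>
      <property>
        <name>Date</name>
        <type>date</type>
        <id>b4c0e36d-08a0-4ed3-b567-b9f26cac5daa</id>
        <value>2000-01-02</value>
      </property>
      <property>
        <name>Weight</name>
        <type>float</type>
        <unit>g</unit>
        <id>ce354924-56c7-4eea-93a8-0ee4438d3106</id>
        <value>5.5</value>
      </property>
      <property>
        <name>Experimenter</name>
        <type>string</type>
        <id>4a24a3ab-3394-4646-b6a6-b5f011f8ef68</id>
        <value>Bob</value>
      </property>
      <property>
        <name>Comment</name>
        <type>text</type>
        <id>9db3446f-d827-4fab-8f2c-d7c4836956ae</id>
        <value>Small scratch at the right ear</value>
      </property>
    </section>
  </section>
</odML>
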