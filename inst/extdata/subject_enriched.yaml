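Document:
  version: '1.4'
  sections:
  - name: Subject
    type: subject
    id: 02b7baf9-5e38-4646-b52e-160003ff532e
    properties: []
    sections:
    - name: Scores_2000-01-01
      type: scores
      id: 20556d0f-83d5-4439-9f6a-db2c056c1d75
      properties:
      - name: Date
        type: date
        id: 88add0c2-df00-4278-978b-8e0844a3231f
        values:
        - '2000-01-01'
      - name: Weight
        type: float
        unit: g
        id: 66f9156d-4ac3-4884-8739-5967adaf4ee8
        values:
        - '5.0'
      - name: Experimenter
        type: string
        id: d3d16078-7d24-418e-a57c-098fa5ab84ee
        values:
        - Alice
      - name: Comment
        type: text
        id: eba9398b-79d7-44e9-8fcc-3556a2dd1db9
        values:
        - Blood sample was taken [...]
      sections: []
    - name: Scores_2000-01-02
      type: scores
      id: bce42fbf-6e7f-4024-8195-535a3cc85a71
      properties:
      - name: Date
        type: date
        id: b4c0e36d-08a0-4ed3-b567-b9f26cac5daa
        values:
        - '2000-01-02'
      - name: Weight
        type: float
        unit: g
        id: ce354924-56c7-4eea-93a8-0ee4438d3106
        values:
        - '5.5'
      - name: Experimenter
        type: string
        id: 4a24a3ab-3394-4646-b6a6-b5f011f8ef68
        values:
        - Bob
      - name: Comment
        type: text
        id: 9db3446f-d827-4fab-8f2c-d7c4836956ae
        values:
        - Small scratch at the right ear
      sections: []
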