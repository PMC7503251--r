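CaseID,Activity,Timestamp,Type,Resource,Emergency,PatientID
1,Entry,01/02/2018 19:05,Complete,John,3,P1
1,Treatment,01/02/2018 19:17,Complete,Jane,3,P1
1,Consultation,01/02/2018 19:20,Start,Tom,3,P1
2,Entry,01/02/2018 19:21,Complete,John,1,P2
2,Treatment,01/02/2018 19:36,Complete,Jane,1,P2
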