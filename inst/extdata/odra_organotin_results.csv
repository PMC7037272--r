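sample_id,localization,analyte,reported
S1,Szczecin Shipyard,TBT,3296
S1,Szczecin Shipyard,TPhT,<5
S2,Gunica River,TBT,3884
S2,Gunica River,TPhT,<5
S3,Elevator Ewa,TBT,142
S3,Elevator Ewa,TPhT,90
S4,Swieta River,TBT,1016
S4,Swieta River,TPhT,<5
S5,Dabie Lake,TBT,345
S5,Dabie Lake,TPhT,<5
S6,Piast Canal,TBT,213
S6,Piast Canal,TPhT,<5
S7,Larpia River Police,TBT,220
S7,Larpia River Police,TPhT,<5
S8,Szczecin Harbor,TBT,750
S8,Szczecin Harbor,TPhT,<5
S9,Szczecin Dabie Marina Club,TBT,193
S9,Szczecin Dabie Marina Club,TPhT,<5
S10,Szczecin West Odra River,TBT,5263
S10,Szczecin West Odra River,TPhT,9
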