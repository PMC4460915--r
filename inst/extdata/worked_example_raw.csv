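CaptureEventID,ClassificationID,UserID,Species,Count,Standing,Resting,Moving,Eating,Interacting,Babies
ASG0010cz5,ASG0010cz5_c01,user001,giraffe,1,N,N,Y,N,N,N
ASG0010cz5,ASG0010cz5_c02,user002,giraffe,1,N,N,Y,N,N,N
ASG0010cz5,ASG0010cz5_c03,user003,giraffe,1,N,N,Y,N,N,N
ASG0010cz5,ASG0010cz5_c04,user004,giraffe,1,N,N,Y,N,N,N
ASG0010cz5,ASG0010cz5_c05,user005,giraffe,1,N,N,Y,N,N,N
ASG0010cz5,ASG0010cz5_c06,user006,giraffe,1,N,N,Y,N,N,N
ASG0010cz5,ASG0010cz5_c07,user007,giraffe,1,N,N,Y,N,N,N
ASG0010cz5,ASG0010cz5_c08,user008,giraffe,1,N,N,Y,N,N,N
ASG0010cz5,ASG0010cz5_c09,user009,giraffe,1,N,N,Y,N,N,N
ASG0010cz5,ASG0010cz5_c10,user010,giraffe,1,Y,N,N,N,N,N
ASG0000009,ASG0000009_c01,user001,spotted hyena,1,N,N,Y,N,N,N
ASG0000009,ASG0000009_c02,user002,jackal,1,N,N,Y,N,N,N
ASG0000009,ASG0000009_c03,user003,spotted hyena,1,N,N,Y,N,N,N
ASG0000009,ASG0000009_c04,user004,warthog,1,Y,N,N,N,N,N
ASG0000009,ASG0000009_c05,user005,spotted hyena,1,Y,N,N,N,N,N
ASG0000009,ASG0000009_c06,user006,spotted hyena,1,N,N,Y,N,N,N
ASG0000009,ASG0000009_c07,user007,spotted hyena,1,N,N,Y,N,N,N
ASG0000009,ASG0000009_c08,user008,spotted hyena,1,N,N,Y,N,N,N
ASG0000009,ASG0000009_c09,user009,warthog,1,N,N,Y,N,N,N
ASG0000009,ASG0000009_c10,user010,spotted hyena,1,N,N,Y,N,N,N
ASG0000009,ASG0000009_c11,user011,wildcat,1,N,N,Y,N,N,N
ASG0000009,ASG0000009_c12,user012,spotted hyena,1,N,N,Y,N,N,N
ASG0000009,ASG0000009_c13,user013,spotted hyena,1,N,N,Y,N,N,N
ASG0000009,ASG0000009_c14,user014,spotted hyena,1,N,N,Y,N,N,N
ASG000xzxd,ASG000xzxd_c01,user001,impala,1,Y,N,N,N,N,N
ASG000xzxd,ASG000xzxd_c02,user002,G. gazelle,1,N,N,Y,N,N,N
ASG000xzxd,ASG000xzxd_c03,user003,reedbuck,1,Y,N,N,N,N,N
ASG000xzxd,ASG000xzxd_c04,user004,reedbuck,1,Y,N,N,N,N,N
ASG000xzxd,ASG000xzxd_c05,user005,dik dik,1,Y,N,Y,N,N,N
ASG000xzxd,ASG000xzxd_c06,user006,blank,,,,,,,
ASG000xzxd,ASG000xzxd_c07,user007,dik dik,1,Y,N,N,N,N,N
ASG000xzxd,ASG000xzxd_c08,user008,impala,1,Y,N,N,N,N,N
ASG000xzxd,ASG000xzxd_c09,user009,blank,,,,,,,
ASG000xzxd,ASG000xzxd_c10,user010,reedbuck,1,Y,N,N,N,N,N
ASG000xzxd,ASG000xzxd_c11,user011,blank,,,,,,,
ASG000xzxd,ASG000xzxd_c12,user012,impala,1,Y,N,N,N,N,N
ASG000xzxd,ASG000xzxd_c13,user013,impala,1,Y,N,N,N,N,N
ASG000xzxd,ASG000xzxd_c14,user014,dik dik,1,Y,N,N,N,N,N
ASG000xzxd,ASG000xzxd_c15,user015,T. gazelle,1,Y,N,N,N,N,N
ASG000xzxd,ASG000xzxd_c16,user016,G. gazelle,1,Y,N,N,N,N,N
ASG000xzxd,ASG000xzxd_c17,user017,G. gazelle,1,Y,N,N,N,N,N
ASG000xzxd,ASG000xzxd_c18,user018,impala,1,Y,N,N,N,N,N
ASG000xzxd,ASG000xzxd_c19,user019,T. gazelle,1,Y,N,N,N,N,N
ASG000xzxd,ASG000xzxd_c20,user020,T. gazelle,1,Y,N,N,N,N,N
ASG000xzxd,ASG000xzxd_c21,user021,dik dik,1,Y,N,N,N,N,N
ASG000xzxd,ASG000xzxd_c22,user022,waterbuck,1,Y,N,N,N,N,N
ASG000xzxd,ASG000xzxd_c23,user023,G. gazelle,1,Y,N,N,N,N,N
ASG000xzxd,ASG000xzxd_c24,user024,G. gazelle,1,Y,N,N,N,N,N
ASG000xzxd,ASG000xzxd_c25,user025,dik dik,1,Y,N,N,N,N,N
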