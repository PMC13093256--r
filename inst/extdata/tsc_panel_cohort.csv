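subject_id,strain,tsc,sex,fold
M01,BXD87,Het,F,0
M02,BXD87,Het,F,0
M03,BXD87,Het,F,0
M04,BXD87,Het,F,1
M05,BXD87,Het,F,1
M06,BXD87,Het,F,1
M07,BXD87,Het,F,1
M08,BXD87,Het,M,0
M09,BXD87,Het,M,0
M10,BXD87,Het,M,1
M11,BXD87,WT,F,0
M12,BXD87,WT,F,1
M13,BXD87,WT,M,0
M14,BXD87,WT,M,0
M15,BXD87,WT,M,1
M16,BXD87,WT,M,1
M17,BXD87,WT,M,1
M18,C57B6,Het,F,0
M19,C57B6,Het,F,0
M20,C57B6,Het,F,0
M21,C57B6,Het,F,1
M22,C57B6,Het,M,1
M23,C57B6,Het,M,1
M24,C57B6,WT,F,0
M25,C57B6,WT,F,0
M26,C57B6,WT,F,0
M27,C57B6,WT,F,0
M28,C57B6,WT,F,1
M29,C57B6,WT,F,1
M30,C57B6,WT,M,1
M31,C57B6,WT,M,1
M32,DBA2,Het,F,0
M33,DBA2,Het,F,1
M34,DBA2,Het,F,1
M35,DBA2,Het,F,1
M36,DBA2,Het,M,0
M37,DBA2,Het,M,0
M38,DBA2,WT,F,0
M39,DBA2,WT,F,0
M40,DBA2,WT,F,0
M41,DBA2,WT,M,0
M42,DBA2,WT,M,1
M43,DBA2,WT,M,1
M44,DBA2,WT,M,1
M45,DBA2,WT,M,1
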