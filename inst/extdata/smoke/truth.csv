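mpi,lab_code,specimen_dt,c1,true_stage,submitted_stage,suppressed,month_dropped,emitted
P000002,L01,2018-05-20T03:55,49.1,1,1,FALSE,FALSE,TRUE
P000002,L01,2018-05-20T18:06,48.1,1,1,FALSE,FALSE,TRUE
P000002,L01,2018-07-10T16:50,46,1,1,FALSE,FALSE,TRUE
P000002,L01,2018-07-11T15:05,48.3,1,1,FALSE,FALSE,TRUE
P000002,L01,2018-10-19T21:06,48.2,1,1,FALSE,FALSE,TRUE
P000002,L01,2018-10-22T01:22,70.1,2,2,FALSE,FALSE,TRUE
P000002,L01,2018-10-22T13:06,74.3,2,2,FALSE,FALSE,TRUE
P000002,L01,2018-10-24T04:38,49.9,1,1,FALSE,FALSE,TRUE
P000003,L02,2018-03-14T08:29,128.4,1,1,FALSE,FALSE,TRUE
P000003,L02,2018-03-14T13:01,128.9,1,1,FALSE,FALSE,TRUE
P000003,L02,2018-05-19T20:58,121.2,1,1,FALSE,FALSE,TRUE
P000004,L01,2018-01-10T19:53,371.8,3,3,FALSE,FALSE,TRUE
P000004,L01,2018-01-11T04:15,405.7,3,3,FALSE,FALSE,TRUE
P000005,L01,2018-04-16T18:21,49.4,1,1,TRUE,FALSE,FALSE
P000005,L01,2018-04-18T15:37,66.8,2,2,FALSE,FALSE,TRUE
P000005,L01,2018-04-18T15:50,64,2,2,FALSE,FALSE,TRUE
P000005,L01,2018-04-20T16:15,50.3,1,1,FALSE,FALSE,TRUE
P000005,L01,2018-05-09T07:49,84,2,2,FALSE,FALSE,TRUE
P000005,L01,2018-05-11T18:59,166,3,3,FALSE,FALSE,TRUE
P000005,L01,2018-05-11T21:29,160.8,3,3,FALSE,FALSE,TRUE
P000005,L01,2018-05-13T11:16,108.9,3,3,TRUE,FALSE,FALSE
P000005,L01,2018-05-15T13:15,63.8,1,1,FALSE,FALSE,TRUE
P000006,L01,2018-07-16T10:59,75.1,1,1,TRUE,FALSE,FALSE
P000006,L01,2018-07-16T17:19,79.5,1,1,FALSE,FALSE,TRUE
P000006,L01,2018-07-18T13:40,65.4,1,1,FALSE,FALSE,TRUE
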