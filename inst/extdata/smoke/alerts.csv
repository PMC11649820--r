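mpi,lab_code,alert_dt,stage,scr_at_alert
P000002,L01,2018-05-20T03:55,1,49.1
P000002,L01,2018-05-20T18:06,1,48.1
P000002,L01,2018-07-10T16:50,1,46
P000002,L01,2018-07-11T15:05,1,48.3
P000002,L01,2018-10-19T21:06,1,48.2
P000002,L01,2018-10-22T01:22,2,70.1
P000002,L01,2018-10-22T13:06,2,74.3
P000002,L01,2018-10-24T04:38,1,49.9
P000003,L02,2018-03-14T08:29,1,128.4
P000003,L02,2018-03-14T13:01,1,128.9
P000003,L02,2018-05-19T20:58,1,121.2
P000004,L01,2018-01-10T19:53,3,371.8
P000004,L01,2018-01-11T04:15,3,405.7
P000005,L01,2018-04-18T15:37,2,66.8
P000005,L01,2018-04-18T15:50,2,64
P000005,L01,2018-04-20T16:15,1,50.3
P000005,L01,2018-05-09T07:49,2,84
P000005,L01,2018-05-11T18:59,3,166
P000005,L01,2018-05-11T21:29,3,160.8
P000005,L01,2018-05-15T13:15,1,63.8
P000006,L01,2018-07-16T17:19,1,79.5
P000006,L01,2018-07-18T13:40,1,65.4
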