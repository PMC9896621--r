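hit_id,nci_code,captured_by,xgb_active,xgb_inactive,xgb_percent_printed,rf_active,rf_inactive,rf_percent_printed
317,3590,"1,2",183,31,85.5,78,30,72.2
318,20261,1,40,77,34.2,NA,NA,NA
319,59407,1,205,34,85.8,NA,NA,NA
320,65832,1,65,56,53.7,NA,NA,NA
321,745104,"1,2",3,3,50.0,5,1,33.3
322,72868,1,56,45,55.4,NA,NA,NA
323,77028,1,52,64,44.8,NA,NA,NA
324,77029,1,47,64,42.3,NA,NA,NA
325,82523,1,152,20,88.4,NA,NA,NA
326,98711,1,48,71,40.3,NA,NA,NA
327,100791,1,70,38,64.8,NA,NA,NA
328,107137,1,102,41,71.3,NA,NA,NA
329,107139,2,NA,NA,NA,45,11,80.4
330,267431,"1,2",40,48,45.5,48,37,56.5
331,289523,1,76,28,73.1,NA,NA,NA
332,338310,2,NA,NA,NA,129,34,79.1
333,341076,"1,2",217,39,84.8,189,29,86.7
334,341077,"1,2",209,41,83.6,180,37,82.9
335,363007,2,NA,NA,NA,119,42,73.9
336,372667,"1,2",158,26,85.9,131,40,76.6
337,373233,1,53,55,49.1,NA,NA,NA
338,380962,1,45,33,57.7,NA,NA,NA
339,645793,2,NA,NA,NA,40,23,63.5
340,651016,2,NA,NA,NA,52,33,61.2
341,669269,"1,2",135,54,71.4,124,33,79.0
342,722969,2,NA,NA,NA,51,20,71.8
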