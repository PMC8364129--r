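{"vertices":[{"id":"c","label":"C"},{"id":"a1","label":"C"},{"id":"a2","label":"C"},{"id":"a3","label":"C"},{"id":"a4","label":"C"},{"id":"d1","label":"C"},{"id":"d2","label":"C"},{"id":"b1","label":"C"},{"id":"b2","label":"C"},{"id":"b3","label":"C"},{"id":"b4","label":"C"},{"id":"y1","label":"C"},{"id":"w1","label":"C"},{"id":"a5","label":"C"},{"id":"x1","label":"C"},{"id":"z1","label":"C"},{"id":"d3","label":"C"},{"id":"z2","label":"C"},{"id":"b5","label":"C"},{"id":"y2","label":"C"},{"id":"w2","label":"C"}],"edges":[{"u":"c","v":"a1","m":1},{"u":"a1","v":"a2","m":1},{"u":"a2","v":"a3","m":1},{"u":"a3","v":"a4","m":1},{"u":"a4","v":"a5","m":1},{"u":"a3","v":"x1","m":1},{"u":"a3","v":"z1","m":1},{"u":"a2","v":"d1","m":1},{"u":"d1","v":"d2","m":1},{"u":"d2","v":"d3","m":1},{"u":"d2","v":"z2","m":1},{"u":"c","v":"b1","m":1},{"u":"b1","v":"b2","m":1},{"u":"b2","v":"b3","m":1},{"u":"b3","v":"b4","m":1},{"u":"b4","v":"b5","m":1},{"u":"b2","v":"y1","m":1},{"u":"y1","v":"y2","m":1},{"u":"b3","v":"w1","m":1},{"u":"w1","v":"w2","m":1}]}
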