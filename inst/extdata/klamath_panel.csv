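taxon,module,mean,min,max,high_mean,low_mean,certainty_mean,rating
Pacific lamprey,baseline,21.8,20,24,28.5,19.5,20.0,2
Klamath River lamprey,baseline,28.5,19,32,31.5,24.8,12.5,3-
Western brook lamprey,baseline,29.3,26,33,32.3,24.0,12.3,3
Northern green sturgeon,baseline,27.5,26,29,31.8,24.3,19.5,3
Klamath speckled dace,baseline,34.0,31,35,35.8,33.3,19.3,4-
Klamath smallscale sucker,baseline,34.0,33,35,36.8,32.0,20.5,4-
Eulachon,baseline,17.5,16,18,24.0,17.3,21.3,2-
Upper Klamath-Trinity fall Chinook salmon,baseline,22.5,20,24,26.5,19.8,25.3,2
Upper Klamath-Trinity spring Chinook salmon,baseline,16.5,15,18,19.0,15.3,27.0,1+
Southern Oregon Northern California coast fall Chinook salmon,baseline,24.5,21,27,29.3,21.3,22.3,2+
Southern Oregon Northern California coast coho salmon,baseline,13.5,13,14,17.5,12.0,26.0,1
Pink salmon,baseline,17.0,15,19,24.3,15.5,18.0,1+
Chum salmon,baseline,19.5,18,22,25.5,16.8,14.8,2
Klamath Mountains Province winter steelhead,baseline,24.8,21,27,28.3,20.5,21.8,2+
Klamath Mountains Province summer steelhead,baseline,16.5,15,17,21.8,14.8,23.5,1
Coastal cutthroat trout,baseline,27.3,25,29,31.5,23.5,19.0,3-
Lower Klamath marbled sculpin,baseline,32.0,32,32,33.0,28.8,14.3,3
Coastal prickly sculpin,baseline,35.5,33,37,35.5,29.8,24.5,4-
Coastrange sculpin,baseline,31.8,31,32,35.0,27.8,18.5,3
Coastal threespine stickleback,baseline,33.0,31,35,35.0,28.5,20.8,3+
Pacific lamprey,climate,18.8,17,22,24.5,14.5,20.8,2
Klamath River lamprey,climate,17.8,15,20,21.5,14.5,12.0,2-
Western brook lamprey,climate,16.8,15,18,22.0,14.0,16.5,1+
Northern green sturgeon,climate,17.8,16,20,21.5,14.3,22.3,2-
Klamath speckled dace,climate,24.0,23,25,29.5,22.5,17.3,3
Klamath smallscale sucker,climate,26.8,24,28,30.8,14.3,22.3,3+
Eulachon,climate,18.8,15,20,24.3,16.0,20.8,2-
Upper Klamath-Trinity fall Chinook salmon,climate,17.3,16,18,21.8,14.3,24.5,2-
Upper Klamath-Trinity spring Chinook salmon,climate,14.8,14,15,19.3,13.8,25.5,1
Southern Oregon Northern California coast fall Chinook salmon,climate,17.5,17,18,20.5,14.3,24.8,2
Southern Oregon Northern California coast coho salmon,climate,15.0,14,16,18.3,13.8,27.3,1
Pink salmon,climate,17.3,16,19,21.5,14.8,20.5,2-
Chum salmon,climate,17.5,17,18,20.5,14.5,21.0,2
Klamath Mountains Province winter steelhead,climate,20.8,18,24,22.3,16.5,25.3,2+
Klamath Mountains Province summer steelhead,climate,13.0,11,16,17.0,11.5,24.5,1
Coastal cutthroat trout,climate,16.8,16,18,22.5,14.0,22.8,1+
Lower Klamath marbled sculpin,climate,20.3,19,21,24.8,17.0,16.3,2
Coastal prickly sculpin,climate,26.5,26,28,28.5,22.3,22.5,3+
Coastrange sculpin,climate,21.5,20,23,24.3,17.0,22.0,2+
Coastal threespine stickleback,climate,23.8,22,26,27.5,20.8,19.0,3-
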