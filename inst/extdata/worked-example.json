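{"name":"worked-example","areas":[{"id":1,"individuals":10},{"id":2,"individuals":20},{"id":3,"individuals":20}],"vehicles":[{"id":1,"capacity":15},{"id":2,"capacity":15}],"times":{"origin_to_area":[[5,11,12],[7,10,12]],"between_areas":[[[0,10,12],[10,0,8],[12,8,0]],[[0,10,12],[10,0,8],[12,8,0]]],"area_to_region":[[6,5,10],[6,5,10]],"loading_interval":[[0.5,0.5,0.5],[0.5,0.5,0.5]]}}
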