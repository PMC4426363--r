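host_gene	mirnas
Sfmbt2	miR669a-3;miR467d;miR669a-2.5;miR297b;miR669a-2.2;miR669e;miR669a-2.9;miR467a-1.9;miR466;miR466g;miR467a-1.5;miR4660;miR669a-2.8;miR467a-1.10;miR297a-3;miR669a-2.7;miR467a-1.1;miR669h;miR669a-2.1;miR669g;miR669a-1;miR699p-1.1;miR669c;miR467a-1.6;miR669m-1;miR669a-2.4;miR669a-2.10;miR699p-1.2;miR467a-1.2;miR669k;miR467a-1.8;miR669a-2.6;miR467a-3;miR669a-2.3;miR669i;miR467a-1.7;miR669b;miR467b;miR669j;miR467a-1.3;miR467a-1.4
Mest	miR335
Usp29	miR3099
H19	miR675
Meg3	miR1906-1;miR770
Mirg	miR377;miR134;miR496;miR154;miR412;miR485;miR382;miR410;miR668;miR3072;miR453;miR409;miR541;miR369
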