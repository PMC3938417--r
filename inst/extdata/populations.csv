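"locus","population","level","parent"
"cytb","Europe","continent",NA
"cytb","Denmark","country","Europe"
"cytb","France","country","Europe"
"cytb","Germany","country","Europe"
"cytb","Sweden","country","Europe"
"cytb","Asia","continent",NA
"cytb","Cambodia","country","Asia"
"cytb","China","country","Asia"
"cytb","Indonesia","country","Asia"
"cytb","Japan","country","Asia"
"cytb","Thailand","country","Asia"
"cytb","Vietnam","country","Asia"
"cytb","Africa","continent",NA
"cytb","South Africa","country","Africa"
"cytb","North America","continent",NA
"cytb","USA","country","North America"
"cytb","French Polynesia","continent",NA
"cytb","Society Islands","country","French Polynesia"
"cytb","Inbred strains","strain",NA
"cytb","All","total",NA
"dloop","Europe","continent",NA
"dloop","Denmark","country","Europe"
"dloop","France","country","Europe"
"dloop","Germany","country","Europe"
"dloop","Sweden","country","Europe"
"dloop","Asia","continent",NA
"dloop","China","country","Asia"
"dloop","Japan","country","Asia"
"dloop","Vietnam","country","Asia"
"dloop","Africa","continent",NA
"dloop","Egypt","country","Africa"
"dloop","North America","continent",NA
"dloop","USA","country","North America"
"dloop","French Polynesia","continent",NA
"dloop","Society Islands","country","French Polynesia"
"dloop","Tubai","country","French Polynesia"
"dloop","Inbred strains","strain",NA
"dloop","All","total",NA
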