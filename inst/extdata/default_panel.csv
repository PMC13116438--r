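"name","class","mw","role","parent","excretion_fraction","is_name","q1","q3_quant","q3_confirm","ce1","ce2"
"6-acetylmorphine","opioid",327.38,"metabolite","heroin",0.013,"heroin-d3",328.4,,,,
"buprenorphine","opioid",467.64,"parent",,0.01,"buprenorphine-d9",468.6,,,,
"carfentanil","opioid",394.51,"parent",,,"fentanyl-d5",395.5,,,,
"codeine","opioid",299.36,"parent",,0.3,"codeine-d3",300.4,,,,
"desomorphine","opioid",271.35,"parent",,,"codeine-d3",272.4,,,,
"etonitazene","opioid",396.53,"parent",,,"etonitazene-13c6",397.5,,,,
"fentanyl","opioid",336.47,"parent",,0.08,"fentanyl-d5",337.5,,,,
"heroin","opioid",369.41,"parent",,,"heroin-d3",370.4,,,,
"isotonitazene","opioid",410.55,"parent",,,"isotonitazene-13c6",411.6,,,,
"methadone","opioid",309.45,"parent",,0.275,"methadone-d9",310.5,,,,
"norbuprenorphine","opioid",413.55,"metabolite","buprenorphine",0.09,"norbuprenorphine-d3",414.6,,,,
"norfentanyl","opioid",232.32,"metabolite","fentanyl",0.32,"norfentanyl-d5",233.3,,,,
"noroxycodone","opioid",301.34,"metabolite","oxycodone",0.23,"noroxycodone-d3",302.3,,,,
"oxycodone","opioid",315.36,"parent",,0.1,"oxycodone-d3",316.4,,,,
"para-fluorofentanyl","opioid",354.46,"parent",,,"fentanyl-d5",355.5,,,,
"amphetamine","stimulant",135.21,"parent",,0.3,"amphetamine-d8",136.2,,,,
"methamphetamine","stimulant",149.23,"parent",,0.43,"methamphetamine-d8",150.2,,,,
"4-hydroxymethamphetamine","stimulant",165.23,"metabolite","methamphetamine",0.15,"methamphetamine-d8",166.2,,,,
"3,4-methylenedioxymethamphetamine","stimulant",193.25,"parent",,0.26,"methamphetamine-d8",194.3,,,,
"cocaine","stimulant",303.35,"parent",,0.08,"cocaine-d3",304.4,,,,
"benzoylecgonine","stimulant",289.33,"metabolite","cocaine",0.35,"benzoylecgonine-d3",290.3,,,,
"cocaethylene","stimulant",317.38,"metabolite","cocaine",0.02,"cocaine-d3",318.4,,,,
"methylphenidate","stimulant",233.31,"parent",,0.01,"amphetamine-d8",234.3,,,,
"propylhexedrine","stimulant",155.28,"parent",,,"methamphetamine-d8",156.3,,,,
"caffeine","stimulant",194.19,"parent",,0.01,"amphetamine-d8",195.2,,,,
"phentermine","stimulant",149.23,"parent",,0.3,"amphetamine-d8",150.2,,,,
"alprazolam","benzodiazepine",308.77,"parent",,0.2,"alprazolam-d5",309.8,,,,
"clonazepam","benzodiazepine",315.71,"parent",,,"alprazolam-d5",316.7,,,,
"etizolam","benzodiazepine",342.85,"parent",,,"alprazolam-d5",343.9,,,,
"flualprazolam","benzodiazepine",326.76,"parent",,,"alprazolam-d5",327.8,,,,
"flunitrazepam","benzodiazepine",313.28,"parent",,,"alprazolam-d5",314.3,,,,
"3,4-methylenedioxypyrovalerone","synthetic_cathinone",275.34,"parent",,,"methamphetamine-d8",276.3,,,,
"alpha-pyrrolidinopentiophenone","synthetic_cathinone",231.33,"parent",,,"methamphetamine-d8",232.3,,,,
"ethylone","synthetic_cathinone",221.25,"parent",,,"methamphetamine-d8",222.3,,,,
"eutylone","synthetic_cathinone",235.28,"parent",,,"methamphetamine-d8",236.3,,,,
"n,n-dimethylpentylone","synthetic_cathinone",249.31,"parent",,,"methamphetamine-d8",250.3,,,,
"ketamine","dissociative",237.73,"parent",,0.02,"ketamine-d4",238.7,,,,
"phencyclidine","dissociative",243.39,"parent",,0.1,"ketamine-d4",244.4,,,,
"eddp","other",277.41,"metabolite","methadone",0.25,"eddp-d3",278.4,,,,
"norketamine","other",223.7,"metabolite","ketamine",0.016,"norketamine-d4",224.7,,,,
"xylazine","other",220.33,"parent",,0.08,"xylazine-d6",221.3,,,,
"4-hydroxyxylazine","other",236.33,"metabolite","xylazine",0.1,"4-hydroxyxylazine-d6",237.3,,,,
"gabapentin","other",171.24,"parent",,0.95,"amphetamine-d8",172.2,,,,
"methaqualone","other",250.3,"parent",,,"alprazolam-d5",251.3,,,,
"mitragynine","other",398.5,"parent",,,"methadone-d9",399.5,,,,
"naloxone","other",327.37,"parent",,0.3,"naloxone-d5",328.4,,,,
"oseltamivir","other",312.4,"parent",,0.05,"naloxone-d5",313.4,,,,
"zolpidem","other",307.39,"parent",,0.01,"alprazolam-d5",308.4,,,,
"pentachlorophenol","other",266.34,"parent",,,"naloxone-d5",267.3,,,,
"naproxen","other",230.26,"parent",,0.1,"naloxone-d5",231.3,,,,
"phenacetin","other",179.22,"parent",,,"naloxone-d5",180.2,,,,
"tianeptine","other",436.95,"parent",,,"naloxone-d5",438,,,,
"amphetamine-d8",,143.26,"internal_standard","amphetamine",,,144.3,,,,
"methamphetamine-d8",,157.28,"internal_standard","methamphetamine",,,158.3,,,,
"benzoylecgonine-d3",,292.35,"internal_standard","benzoylecgonine",,,293.4,,,,
"cocaine-d3",,306.37,"internal_standard","cocaine",,,307.4,,,,
"fentanyl-d5",,341.5,"internal_standard","fentanyl",,,342.5,,,,
"norfentanyl-d5",,237.35,"internal_standard","norfentanyl",,,238.4,,,,
"methadone-d9",,318.51,"internal_standard","methadone",,,319.5,,,,
"eddp-d3",,280.43,"internal_standard","eddp",,,281.4,,,,
"heroin-d3",,372.43,"internal_standard","heroin",,,373.4,,,,
"ketamine-d4",,241.75,"internal_standard","ketamine",,,242.8,,,,
"norketamine-d4",,227.72,"internal_standard","norketamine",,,228.7,,,,
"buprenorphine-d9",,476.69,"internal_standard","buprenorphine",,,477.7,,,,
"norbuprenorphine-d3",,416.57,"internal_standard","norbuprenorphine",,,417.6,,,,
"naloxone-d5",,332.4,"internal_standard","naloxone",,,333.4,,,,
"oxycodone-d3",,318.38,"internal_standard","oxycodone",,,319.4,,,,
"noroxycodone-d3",,304.36,"internal_standard","noroxycodone",,,305.4,,,,
"xylazine-d6",,226.37,"internal_standard","xylazine",,,227.4,,,,
"4-hydroxyxylazine-d6",,242.37,"internal_standard","4-hydroxyxylazine",,,243.4,,,,
"etonitazene-13c6",,402.48,"internal_standard","etonitazene",,,403.5,,,,
"isotonitazene-13c6",,416.51,"internal_standard","isotonitazene",,,417.5,,,,
"codeine-d3",,302.38,"internal_standard","codeine",,,303.4,,,,
"alprazolam-d5",,313.8,"internal_standard","alprazolam",,,314.8,,,,
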