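region,macro_region
Piedmont,North
Valle d'Aosta,North
Liguria,North
Lombardy,North
Trentino-Alto Adige,North
Veneto,North
Friuli-Venezia Giulia,North
Emilia-Romagna,North
Tuscany,Central
Umbria,Central
Marche,Central
Lazio,Central
Abruzzo,South
Molise,South
Campania,South
Apulia,South
Basilicata,South
Calabria,South
Sicily,Sicily
Sardinia,Sardinia
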