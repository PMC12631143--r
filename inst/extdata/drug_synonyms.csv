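variant,generic
methotrexate,methotrexate
mtx,methotrexate
trexall,methotrexate
rheumatrex,methotrexate
otrexup,methotrexate
rasuvo,methotrexate
methotrexate sodium,methotrexate
metotrexate,methotrexate
methotrexat,methotrexate
amethopterin,methotrexate
folic acid,folic acid
folvite,folic acid
folacin,folic acid
prednisone,prednisone
deltasone,prednisone
adalimumab,adalimumab
humira,adalimumab
ibuprofen,ibuprofen
advil,ibuprofen
motrin,ibuprofen
hydroxychloroquine,hydroxychloroquine
plaquenil,hydroxychloroquine
sulfasalazine,sulfasalazine
azulfidine,sulfasalazine
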