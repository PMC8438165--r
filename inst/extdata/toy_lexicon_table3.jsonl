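{"phrase_id":"toy001","words":[{"orth_id":"did","pos":"Verb","phones":["sh","i0","t","a"]}]}
{"phrase_id":"toy002","words":[{"orth_id":"did","pos":"Verb","phones":["sh","i0","t","a"]}]}
{"phrase_id":"toy003","words":[{"orth_id":"did","pos":"Verb","phones":["sh","i0","t","a"]}]}
{"phrase_id":"toy004","words":[{"orth_id":"did","pos":"Verb","phones":["sh","i0","t","a"]}]}
{"phrase_id":"toy005","words":[{"orth_id":"did","pos":"Verb","phones":["sh","i0","t","a"]}]}
{"phrase_id":"toy006","words":[{"orth_id":"did","pos":"Verb","phones":["sh","i0","t","a"]}]}
{"phrase_id":"toy007","words":[{"orth_id":"did","pos":"Verb","phones":["sh","i0","t","a"]}]}
{"phrase_id":"toy008","words":[{"orth_id":"did","pos":"Verb","phones":["sh","t","a"]}]}
{"phrase_id":"toy009","words":[{"orth_id":"did","pos":"Verb","phones":["sh","t","a"]}]}
{"phrase_id":"toy010","words":[{"orth_id":"did","pos":"Verb","phones":["sh","i","t","a"]}]}
{"phrase_id":"toy011","words":[{"orth_id":"down","pos":"Noun","phones":["sh","i0","t","a"]}]}
{"phrase_id":"toy012","words":[{"orth_id":"down","pos":"Noun","phones":["sh","i0","t","a"]}]}
{"phrase_id":"toy013","words":[{"orth_id":"down","pos":"Noun","phones":["sh","i0","t","a"]}]}
{"phrase_id":"toy014","words":[{"orth_id":"down","pos":"Noun","phones":["sh","i0","t","a"]}]}
{"phrase_id":"toy015","words":[{"orth_id":"down","pos":"Noun","phones":["sh","i","t","a"]}]}
{"phrase_id":"toy016","words":[{"orth_id":"tongue","pos":"Noun","phones":["sh","i0","t","a"]}]}
{"phrase_id":"toy017","words":[{"orth_id":"tongue","pos":"Noun","phones":["sh","t","a"]}]}
{"phrase_id":"toy018","words":[{"orth_id":"aru","pos":"Verb","phones":["a","r","u"]}]}
{"phrase_id":"toy019","words":[{"orth_id":"aru","pos":"Verb","phones":["a","r","u"]}]}
{"phrase_id":"toy020","words":[{"orth_id":"aru","pos":"Verb","phones":["a","r","u"]}]}
{"phrase_id":"toy021","words":[{"orth_id":"aru","pos":"Verb","phones":["a","r","u"]}]}
{"phrase_id":"toy022","words":[{"orth_id":"aru","pos":"Verb","phones":["a","r","u"]}]}
{"phrase_id":"toy023","words":[{"orth_id":"aru","pos":"Verb","phones":["a","r","u"]}]}
{"phrase_id":"toy024","words":[{"orth_id":"aru","pos":"Verb","phones":["a","r","u"]}]}
{"phrase_id":"toy025","words":[{"orth_id":"aru","pos":"Verb","phones":["a","r","u"]}]}
{"phrase_id":"toy026","words":[{"orth_id":"aru","pos":"Verb","phones":["a","r","u"]}]}
{"phrase_id":"toy027","words":[{"orth_id":"aru","pos":"Verb","phones":["a","r","u"]}]}
{"phrase_id":"toy028","words":[{"orth_id":"aru","pos":"Adjective","phones":["a","r","u"]}]}
{"phrase_id":"toy029","words":[{"orth_id":"aru","pos":"Adjective","phones":["a","r","u"]}]}
{"phrase_id":"toy030","words":[{"orth_id":"aru","pos":"Adjective","phones":["a","r","u"]}]}
{"phrase_id":"toy031","words":[{"orth_id":"aru","pos":"Adjective","phones":["a","r","u"]}]}
{"phrase_id":"toy032","words":[{"orth_id":"aru","pos":"Adjective","phones":["a","r","u"]}]}
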