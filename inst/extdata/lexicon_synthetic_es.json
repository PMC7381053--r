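{
  "first_person": ["yo", "me", "mi", "mio", "mia", "conmigo", "estoy"],
  "suicide_explicit": ["quiero morir", "me quiero matar", "quitarme la vida", "suicidarme", "desaparecer para siempre", "acabar con todo"],
  "depression": ["estoy triste", "deprimido", "sin ganas", "llorar", "vacio", "no aguanto mas"],
  "self_loathing": ["me odio", "no valgo nada", "soy un desastre", "soy una carga"],
  "insomnia": ["no puedo dormir", "despierto", "madrugada", "insomnio", "otra noche sin"],
  "anxiety": ["ansiedad", "no puedo respirar", "panico", "ataque de ansiedad"],
  "negation": ["no", "nunca", "nada", "nadie", "jamas"],
  "social_support": ["mis amigos", "apoyo", "familia", "me ayudan"],
  "health": ["salud", "dolor", "hospital", "pastillas", "enfermo", "cuerpo"],
  "work_money": ["trabajo", "dinero", "sueldo", "empleo", "oficina", "pagar"]
}
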