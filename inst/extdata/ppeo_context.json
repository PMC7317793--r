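{
  "@context": {
    "ppeo": "https://w3id.org/ppeo/terms#",
    "rdf": "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    "xsd": "http://www.w3.org/2001/XMLSchema#"
  }
}
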