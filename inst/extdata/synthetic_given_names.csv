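name
MARIA
JOSE
ANA
JOAO
ANTONIO
FRANCISCO
CARLOS
PAULO
PEDRO
LUCAS
LUIZ
MARCOS
LUIS
GABRIEL
RAFAEL
FRANCISCA
DANIEL
MARCELO
BRUNO
EDUARDO
FELIPE
RODRIGO
MANOEL
MATEUS
ANDRE
FERNANDO
FABIO
LEONARDO
GUSTAVO
GUILHERME
LEANDRO
TIAGO
VITOR
ALEXANDRE
ADRIANA
JULIANA
MARCIA
FERNANDA
PATRICIA
ALINE
SANDRA
CAMILA
AMANDA
BRUNA
JESSICA
LETICIA
JULIA
LUCIANA
VANESSA
MARIANA
VERA
VITORIA
LARISSA
CLAUDIA
BEATRIZ
RITA
SONIA
RENATA
SIMONE
ANGELA
DANIELA
ROSANGELA
NATALIA
INES
REGINA
TEREZA
CRISTINA
GABRIELA
MONICA
VALERIA
SEBASTIAO
RAIMUNDO
GERALDO
ROBERTO
RICARDO
JORGE
WAGNER
WELLINGTON
DIEGO
THIAGO
SERGIO
CLEITON
EDSON
ELIAS
EMERSON
EVERTON
FLAVIO
GILBERTO
HELIO
IGOR
IVAN
JAIR
JEFFERSON
JONAS
JOSUE
JULIO
KLEBER
MAURICIO
MILTON
MOISES
NELSON
OSVALDO
OTAVIO
RENAN
ROGERIO
RONALDO
RUBENS
SAMUEL
SILAS
VALDIR
WASHINGTON
YURI
ZILDA
IRACEMA
JANDIRA
MARILIA
NEUSA
ODETE
PALMIRA
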