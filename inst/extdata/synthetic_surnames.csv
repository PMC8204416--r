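name
SILVA
SANTOS
OLIVEIRA
SOUZA
RODRIGUES
FERREIRA
ALVES
PEREIRA
LIMA
GOMES
COSTA
RIBEIRO
MARTINS
CARVALHO
ALMEIDA
LOPES
SOARES
FERNANDES
VIEIRA
BARBOSA
ROCHA
DIAS
NASCIMENTO
ANDRADE
MOREIRA
NUNES
MARQUES
MACHADO
MENDES
FREITAS
CARDOSO
RAMOS
GONCALVES
SANTANA
TEIXEIRA
ARAUJO
PINTO
MONTEIRO
MOURA
CAVALCANTI
BATISTA
CORREIA
DUARTE
CASTRO
CAMPOS
MIRANDA
BORGES
REIS
MEDEIROS
TAVARES
AZEVEDO
BARROS
CUNHA
FONSECA
GARCIA
GUIMARAES
HENRIQUES
JESUS
LEAL
MACEDO
NEVES
PACHECO
PAIVA
QUEIROZ
RESENDE
SALES
SIQUEIRA
TORRES
VASCONCELOS
XIMENES
BITTENCOURT
CAMARGO
DANTAS
ESTEVES
FIGUEIREDO
GUEDES
HOLANDA
IGLESIAS
JUSTINO
KLEIN
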