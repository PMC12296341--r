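format-version: 1.2
ontology: mini-go-synthetic

[Term]
id: GO:0000001
name: root process
namespace: biological_process
def: "A synthetic root biological process." [curator:demo]

[Term]
id: GO:0000002
name: child process
namespace: biological_process
def: "A synthetic child process." [curator:demo]
is_a: GO:0000001 ! root process

[Term]
id: GO:0000003
name: grandchild process
namespace: biological_process
def: "A synthetic grandchild process." [curator:demo]
relationship: part_of GO:0000002 ! child process
relationship: regulates GO:0000001 ! root process

[Term]
id: GO:0000004
name: root function
namespace: molecular_function
def: "A synthetic root molecular function." [curator:demo]

[Term]
id: GO:0000005
name: child function
namespace: molecular_function
def: "A synthetic child function." [curator:demo]
is_a: GO:0000004 ! root function

[Term]
id: GO:0000006
name: retired process
namespace: biological_process
def: "An obsolete synthetic process." [curator:demo]
is_obsolete: true
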