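"composition","count","skull_present"
"ST+CB+NB",14,TRUE
"ST+CB+CSF/NB",7,TRUE
"ST+CB+A/CSF+NB",3,TRUE
"ST+CB+CSF+NB",22,TRUE
"ST+CB+A+NB",2,TRUE
"ST+CB+A+BC",1,TRUE
"ST+CB+BC",2,TRUE
"ST+CB+SAH+BC",2,TRUE
"ST+CB+SAH+NB",6,TRUE
"ST+CB+ICH/NB",1,TRUE
"ST+CB+IT",4,TRUE
"ST+A+NB",1,FALSE
"ST+EH+BC",1,FALSE
"ST+EH+IT",3,FALSE
"ST+EH+CSF/IT",2,FALSE
"ST+IT/NB",1,FALSE
"SST+CB+NB",13,TRUE
"SST+CB+CSF/NB",2,TRUE
"SST+CB+CSF/A+NB",1,TRUE
"SST+CB+CSF+NB",10,TRUE
"SST+CB+A+NB",5,TRUE
"SST+CB/A+NB",1,TRUE
"SST+CB+BC",2,TRUE
"SST+CB+CSF/SAH+NB",3,TRUE
"SST+CB+EH+CSF",1,TRUE
"SST+CB+EH+CSF+NB",1,TRUE
"SST+CB",2,TRUE
"SST+CB+EH",1,TRUE
"SST+CSF+CB/A",1,TRUE
"SST+EH+IT",1,FALSE
"SST+CSF+NB",1,FALSE
"SST+IT",1,FALSE
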