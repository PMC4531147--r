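(* Line-oriented grammar of the behavioural DSL (.gubs files, UTF-8).
   Comments run from '#' to end of line.  Blank lines are ignored.
   Rule arrows must be surrounded by whitespace.                        *)

program      = { line } ;
line         = declaration | rule | spot | open-context
             | open-compartment | close | comment | blank ;

declaration  = name , ":" , "{" , decl-items , "}" ;
decl-items   = decl-item , { "," , decl-item } ;
decl-item    = chain | pair ;
chain        = label , "<" , label , { "<" , label } ;   (* at most one *)
pair         = label , "/~" , label ;

rule         = literal-set , arrow , literal-set ;
arrow        = "->" | "o->" | "+->" | "-+" | "--" ;
               (* normal, persistent, remnant, strong activation,
                  strong inhibition *)
literal-set  = literal , { "&" , literal } ;
literal      = [ "!" ] , name , [ qualifier ] ;
qualifier    = "(" , ( label | number ) , ")"
             | "[" , number , "," , number , "]" ;

spot         = "obs_" , label , "::" , literal ;

open-context     = "[" , name , "]" , "{" ;   (* context agent *)
open-compartment = name , "{" ;
close            = "}" ;

name         = letter , { letter | digit | "_" } ;
               (* upper-case first letter: constant;
                  lower-case: variable *)
label        = ( letter | digit | "_" ) , { letter | digit | "_" } ;
number       = [ "-" ] , digit , { digit } , [ "." , { digit } ] ;
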