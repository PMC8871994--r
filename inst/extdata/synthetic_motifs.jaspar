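>SYNPRM1 tata-box-like (synthetic)
A  [ 1 17 1 17 16 15 14 2 ]
C  [ 1 1 1 1 1 2 2 1 ]
G  [ 1 1 1 1 2 2 2 16 ]
T  [ 17 1 17 1 1 1 2 1 ]
>SYNPRM2 gc-box-like (synthetic)
A  [ 1 1 1 1 1 2 1 1 1 ]
C  [ 1 1 1 1 16 1 1 1 2 ]
G  [ 17 17 17 17 2 16 17 17 16 ]
T  [ 1 1 1 1 1 1 1 1 1 ]
>SYNPRM3 caat-box-like (synthetic)
A  [ 1 1 2 2 17 17 1 2 ]
C  [ 2 2 16 16 1 1 1 16 ]
G  [ 16 16 1 1 1 1 2 1 ]
T  [ 1 1 1 1 1 1 16 1 ]
>SYNPRM4 initiator-like (synthetic)
A  [ 1 1 16 1 2 1 2 ]
C  [ 16 16 2 1 16 1 16 ]
G  [ 2 1 1 1 1 1 1 ]
T  [ 1 2 1 17 1 17 1 ]
>SYNPRM5 bre-like (synthetic)
A  [ 1 1 1 1 1 2 1 ]
C  [ 2 16 2 16 2 16 17 ]
G  [ 16 2 16 2 16 1 1 ]
T  [ 1 1 1 1 1 1 1 ]
>SYNENH1 homeobox-like-1 (synthetic)
A  [ 1 1 17 17 1 1 16 2 ]
C  [ 16 1 1 1 1 1 2 1 ]
G  [ 2 1 1 1 1 2 1 16 ]
T  [ 1 17 1 1 17 16 1 1 ]
>SYNENH2 homeobox-like-2 (synthetic)
A  [ 1 2 16 1 1 17 16 1 ]
C  [ 1 1 2 1 1 1 1 2 ]
G  [ 2 16 1 1 2 1 2 1 ]
T  [ 16 1 1 17 16 1 1 16 ]
>SYNENH3 ebox-like (synthetic)
A  [ 1 16 1 1 1 2 1 1 ]
C  [ 16 1 2 16 1 1 1 2 ]
G  [ 2 2 16 1 1 16 1 1 ]
T  [ 1 1 1 2 17 1 17 16 ]
>SYNENH4 cre-like (synthetic)
A  [ 1 1 2 16 1 1 1 2 ]
C  [ 1 1 1 1 16 1 2 16 ]
G  [ 1 17 16 1 1 16 1 1 ]
T  [ 17 1 1 2 2 2 16 1 ]
>SYNENH5 palindrome-like (synthetic)
A  [ 17 16 1 2 1 1 1 1 ]
C  [ 1 1 16 1 1 2 1 1 ]
G  [ 1 2 1 16 16 1 1 2 ]
T  [ 1 1 2 1 2 16 17 16 ]
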