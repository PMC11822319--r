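# Subreddits excluded from post selection: forums about games, popular
# media, and technology where "get tested / get checked" phrasing is almost
# never about health. This list is a user-replaceable reconstruction (the
# original study's full exclusion list is not published); edit freely.
gaming
games
pcgaming
leagueoflegends
fortnite
minecraft
overwatch
pokemon
movies
television
music
hiphopheads
anime
books
sports
nba
nfl
soccer
formula1
technology
programming
buildapc
techsupport
android
apple
cars
politics
worldnews
news
funny
memes
aww
pics
videos
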